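#' Simulation configuration
#'
#' Parameters of the variant-level pooled sequencing simulator. The
#' defaults describe the reference experimental design: a 10 x 10 matrix
#' (pool ploidy 20) sequenced to 100x allelic coverage, i.e. ~2000x per
#' pool, over a gene-panel-sized set of segregating sites with a
#' rare-skewed allele-frequency spectrum.
#'
#' @param nRows,nCols Matrix dimensions (default 10 x 10).
#' @param allelicCoverage Expected reads per haplotype copy in a pool;
#'   pool depth is `2 * poolSize * allelicCoverage` (default 100).
#' @param nSites Number of polymorphic sites segregating in the cohort
#'   (default 800, a desk-scale stand-in for a gene panel).
#' @param afAlpha,afBeta Shape parameters of the Beta allele-frequency
#'   spectrum (default Beta(0.3, 8): median frequency well below 1%, so a
#'   sizeable fraction of sites are private to one individual).
#' @param indelFraction Proportion of sites that are indels (default 0.1,
#'   the typical indel share of germline call sets).
#' @param seqErrorRate Per-base substitution error probability
#'   (default 1e-3).
#' @param fpSiteRate Expected artifact calls per pool, as a fraction of
#'   `nSites` (default 0.15, reproducing the roughly 15-25% raw false
#'   discovery rate seen in high-ploidy pool calling).
#' @param minAltReads,minAltFraction Detection thresholds of the emulated
#'   caller: a site is called in a pool only with at least this many alt
#'   reads and at least this alt-read fraction (defaults 3 and 0.015; a
#'   single copy in a pool of 24 has expected fraction 1/48 ~ 0.021, so
#'   large matrices sit close to the detection limit, as they do in
#'   practice).
#' @param indelDropout Additional per-pool detection-failure probability
#'   for indels, scaled by pool size (`min(0.9, indelDropout * m / 10)`
#'   for a pool of m individuals; default 0.10). This models the
#'   alignment-driven indel losses that grow with pool complexity and are
#'   upstream of a depth model.
#' @param seed Master seed; identical configs reproduce bit-identical
#'   call sets.
#' @return A `SimConfig` object.
#' @export
simConfig <- function(nRows = 10, nCols = 10, allelicCoverage = 100,
                      nSites = 800, afAlpha = 0.3, afBeta = 8,
                      indelFraction = 0.1, seqErrorRate = 1e-3,
                      fpSiteRate = 0.15, minAltReads = 3,
                      minAltFraction = 0.015, indelDropout = 0.10,
                      seed = 1) {
  new("SimConfig", nRows = as.integer(nRows), nCols = as.integer(nCols),
      allelicCoverage = as.numeric(allelicCoverage),
      nSites = as.integer(nSites), afAlpha = afAlpha, afBeta = afBeta,
      indelFraction = indelFraction, seqErrorRate = seqErrorRate,
      fpSiteRate = fpSiteRate, minAltReads = as.integer(minAltReads),
      minAltFraction = minAltFraction, indelDropout = indelDropout,
      seed = as.integer(seed))
}

## evaluate expr under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## deterministic child seed, kept inside 32-bit integer range
.childSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

.randomBases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

#' Draw a synthetic cohort over a synthetic reference contig
#'
#' Generates a random reference contig, places `nSites` well-separated
#' polymorphic sites on it (SNVs and anchored indels in the configured
#' proportion), draws an allele frequency per site from the Beta spectrum,
#' and assigns each individual of the `nRows * nCols` cohort 0/1/2 copies
#' per site with Hardy-Weinberg probabilities, independently across sites.
#' Site keys are produced through [normalizeVariant()], so the truth is
#' already in canonical form.
#'
#' @param config A [simConfig()].
#' @return A `SimTruth` object carrying the sparse genotype table, the
#'   site table (key, allele frequency, vtype) and the contig sequence.
#' @export
sampleCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  .withSeed(config@seed, {
    nSites <- config@nSites
    L <- 18L * nSites + 60L
    contig <- paste(.randomBases(L), collapse = "")
    contigName <- "sim1"
    slots <- seq(10L, L - 12L, by = 18L)
    pos <- sort(sample(slots, nSites))
    isIndel <- runif(nSites) < config@indelFraction
    keys <- character(nSites)
    for (i in seq_len(nSites)) {
      p <- pos[i]
      win <- referenceWindow(contigName, p - 9L,
                             substr(contig, p - 9L, p + 8L))
      refBase <- substr(contig, p, p)
      if (!isIndel[i]) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1L)
        keys[i] <- normalizeVariant(contigName, p, refBase, alt, win)
      } else if (runif(1) < 0.5) {        # deletion of 1-3 bases
        k <- sample(1:3, 1L)
        ref <- substr(contig, p, p + k)
        keys[i] <- normalizeVariant(contigName, p, ref, refBase, win)
      } else {                            # insertion of 1-3 bases
        k <- sample(1:3, 1L)
        alt <- paste0(refBase, paste(.randomBases(k), collapse = ""))
        keys[i] <- normalizeVariant(contigName, p, refBase, alt, win)
      }
    }
    dup <- duplicated(keys)
    if (any(dup)) {   # vanishingly rare with 18 bp spacing
      keys <- keys[!dup]; pos <- pos[!dup]; isIndel <- isIndel[!dup]
      nSites <- length(keys)
    }
    af <- rbeta(nSites, config@afAlpha, config@afBeta)
    layout <- gridLayout(config@nRows, config@nCols)
    samples <- sampleIds(layout)
    n <- length(samples)
    copies <- matrix(rbinom(n * nSites, 2L, rep(af, each = n)),
                     nrow = n, ncol = nSites)
    hit <- which(copies > 0L, arr.ind = TRUE)
    genotypes <- data.frame(sample_id = samples[hit[, 1L]],
                            key = keys[hit[, 2L]],
                            copies = as.integer(copies[hit]),
                            stringsAsFactors = FALSE)
    genotypes <- genotypes[order(genotypes$sample_id, genotypes$key), ]
    rownames(genotypes) <- NULL
    new("SimTruth", genotypes = genotypes,
        siteTable = data.frame(key = keys, af = af,
                               vtype = ifelse(isIndel, "INDEL", "SNV"),
                               stringsAsFactors = FALSE),
        contig = contig, contigName = contigName, config = config)
  })
}

#' Per-individual truth call sets
#'
#' @param truth A `SimTruth`.
#' @return Named list, sample id to character vector of carried keys
#'   (every sample of the cohort grid is present, carriers or not).
#' @export
truthCallSets <- function(truth) {
  cfg <- truth@config
  samples <- sampleIds(gridLayout(cfg@nRows, cfg@nCols))
  g <- truth@genotypes
  out <- split(g$key, factor(g$sample_id, levels = samples))
  lapply(out, as.character)
}

## class-conditional technical annotations; a modeling device with
## lognormal/gamma/normal families, clearly synthetic
.simAnnotations <- function(n, class, depth, altReads) {
  stopifnot(class %in% c("true", "artifact"))
  if (class == "true") {
    df <- data.frame(
      QD = pmin(40, rlnorm(n, log(20), 0.30)),
      FS = rgamma(n, shape = 1.5, scale = 1.3),
      MQ = pmin(60, rnorm(n, 60, 1.2)),
      SOR = rgamma(n, shape = 2, scale = 0.45),
      MQRankSum = rnorm(n, 0, 0.9),
      ReadPosRankSum = rnorm(n, 0, 0.9),
      BaseQRankSum = rnorm(n, 0, 0.9),
      QUAL = altReads * pmax(1, rnorm(n, 30, 6)))
  } else {
    df <- data.frame(
      QD = pmin(40, rlnorm(n, log(4), 0.6)),
      FS = rgamma(n, shape = 2, scale = 8),
      MQ = pmin(60, rnorm(n, 48, 7)),
      SOR = rgamma(n, shape = 3, scale = 1),
      MQRankSum = rnorm(n, -2.2, 1.4),
      ReadPosRankSum = rnorm(n, -2.0, 1.4),
      BaseQRankSum = rnorm(n, -1.5, 1.3),
      QUAL = altReads * pmax(1, rnorm(n, 12, 6)))
  }
  for (col in c("MQRankSum", "ReadPosRankSum", "BaseQRankSum"))
    df[[col]][runif(n) < 0.2] <- NA   # hom-alt-like missingness
  df$DP <- depth
  df$AF <- ifelse(depth > 0, altReads / depth, 0)
  df
}

## one pool's emitted calls + truth labels
.simulateOnePool <- function(truth, members, poolId, axis, index, config) {
  cfg <- config
  m <- length(members)
  emptyCalls <- data.frame(key = character(), vtype = character(),
                           stringsAsFactors = FALSE)
  if (m == 0L)
    return(list(pool = poolCallSet(poolId, axis, index, emptyCalls),
                labels = data.frame(pool_id = character(),
                                    key = character(), label = integer(),
                                    stringsAsFactors = FALSE)))
  ploidy <- 2L * m
  g <- truth@genotypes
  g <- g[g$sample_id %in% members, , drop = FALSE]
  ac <- tapply(g$copies, g$key, sum)
  keys <- names(ac)
  ac <- as.integer(ac)
  nt <- length(keys)
  detected <- logical(nt)
  depth <- integer(nt)
  altReads <- integer(nt)
  if (nt) {
    depth <- rpois(nt, ploidy * cfg@allelicCoverage)
    e <- cfg@seqErrorRate
    pAlt <- (ac / ploidy) * (1 - e) + (1 - ac / ploidy) * e / 3
    altReads <- rbinom(nt, depth, pAlt)
    detected <- depth > 0L & altReads >= cfg@minAltReads &
      altReads / pmax(depth, 1L) >= cfg@minAltFraction
    vt <- truth@siteTable$vtype[match(keys, truth@siteTable$key)]
    dIndel <- min(0.9, cfg@indelDropout * m / 10)
    if (dIndel > 0)
      detected <- detected & !(vt == "INDEL" & runif(nt) < dIndel)
  }
  tKeys <- keys[detected]
  tCalls <- if (length(tKeys)) {
    cbind(data.frame(key = tKeys, vtype = variantType(tKeys),
                     stringsAsFactors = FALSE),
          .simAnnotations(length(tKeys), "true", depth[detected],
                          altReads[detected]))
  } else NULL

  ## recurrent artifact sites: drawn from the shared error-prone panel
  panel <- attr(truth, "artifactPanel")
  nArt <- rpois(1L, cfg@fpSiteRate * cfg@nSites)
  nArt <- min(nArt, nrow(panel))
  aCalls <- NULL
  if (nArt > 0L) {
    art <- panel[sample.int(nrow(panel), nArt), , drop = FALSE]
    aDepth <- rpois(nArt, ploidy * cfg@allelicCoverage)
    frac <- rbeta(nArt, 2, 30)
    aAlt <- rbinom(nArt, aDepth, frac)
    aAlt <- pmax(aAlt, cfg@minAltReads,
                 ceiling(cfg@minAltFraction * aDepth))
    aCalls <- cbind(data.frame(key = art$key, vtype = art$vtype,
                               stringsAsFactors = FALSE),
                    .simAnnotations(nArt, "artifact", aDepth, aAlt))
  }
  calls <- .rbindFill(list(tCalls, aCalls))
  if (is.null(calls)) calls <- emptyCalls
  labels <- data.frame(pool_id = rep(poolId, nrow(calls)),
                       key = calls$key,
                       label = rep(c(1L, 0L),
                                   c(NROW(tCalls), NROW(aCalls))),
                       stringsAsFactors = FALSE)
  dupArt <- duplicated(calls$key)   # artifact colliding with a true call
  calls <- calls[!dupArt, , drop = FALSE]
  labels <- labels[!dupArt, , drop = FALSE]
  rownames(calls) <- rownames(labels) <- NULL
  list(pool = poolCallSet(poolId, axis, index, calls), labels = labels)
}

#' Simulate pooled call sets for a layout
#'
#' For every row and column pool of the layout, draws per-site pool depth
#' as Poisson(`2m * allelicCoverage`) (m = pool size), alt-read counts as
#' Binomial with the pooled allele fraction perturbed by sequencing error,
#' and emits a call when the detection thresholds are met. Indel calls
#' additionally fail with a pool-size-scaled dropout probability. Artifact
#' calls are injected from a panel of recurrent error-prone sites at rate
#' `fpSiteRate * nSites` per pool. Every emitted call carries synthetic
#' class-conditional technical annotations (QD, FS, MQ, SOR, rank sums,
#' DP, AF, QUAL) and a truth label in the returned label table.
#'
#' @param truth A [sampleCohort()] result.
#' @param layout A `MatrixLayout` whose samples all exist in `truth`.
#' @param config The [simConfig()] used for `truth` (or a modified copy;
#'   the seed governs the sequencing noise).
#' @return List with `rowPools`, `colPools` (lists of `PoolCallSet`) and
#'   `labels` (data.frame `pool_id`, `key`, `label` with 1 = true call,
#'   0 = artifact).
#' @export
simulatePoolCalls <- function(truth, layout, config = truth@config) {
  stopifnot(is(truth, "SimTruth"), is(layout, "MatrixLayout"))
  missing <- setdiff(sampleIds(layout), sampleIds(gridLayout(
    truth@config@nRows, truth@config@nCols)))
  if (length(missing))
    stop("layout samples absent from truth: ",
         paste(head(missing, 3L), collapse = ", "))
  .withSeed(.childSeed(config@seed, 104729L), {
    attr(truth, "artifactPanel") <- .artifactPanel(truth)
    cells <- layout@cells
    sim <- list()
    for (i in seq_len(layout@nRows))
      sim[[length(sim) + 1L]] <- .simulateOnePool(
        truth, cells$sample_id[cells$row == i], layout@rowPoolIds[i],
        "ROW", i, config)
    nr <- length(sim)
    for (j in seq_len(layout@nCols))
      sim[[length(sim) + 1L]] <- .simulateOnePool(
        truth, cells$sample_id[cells$col == j], layout@colPoolIds[j],
        "COL", j, config)
    labels <- do.call(rbind, lapply(sim, `[[`, "labels"))
    rownames(labels) <- NULL
    list(rowPools = lapply(sim[seq_len(nr)], `[[`, "pool"),
         colPools = lapply(sim[-seq_len(nr)], `[[`, "pool"),
         labels = labels)
  })
}

## error-prone site panel shared by all pools of a run; positions offset
## from the true sites so keys never collide
.artifactPanel <- function(truth) {
  cfg <- truth@config
  site <- parseVariantKey(truth@siteTable$key)
  pos <- site$pos + 7L
  base <- substr(rep(truth@contig, length(pos)), pos, pos)
  alt <- vapply(base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
  keys <- variantKey(truth@contigName, pos, base, alt)
  isIndel <- runif(length(keys)) < cfg@indelFraction
  if (any(isIndel)) {   # anchored single-base insertions as indel errors
    ins <- .randomBases(sum(isIndel))
    same <- ins == base[isIndel]   # keep keys parsimonious
    ins[same] <- vapply(base[isIndel][same], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
    keys[isIndel] <- variantKey(truth@contigName, pos[isIndel],
                                base[isIndel],
                                paste0(base[isIndel], ins))
  }
  panel <- data.frame(key = keys, vtype = variantType(keys),
                      stringsAsFactors = FALSE)
  panel <- panel[!duplicated(panel$key) &
                   !(panel$key %in% truth@siteTable$key), , drop = FALSE]
  ## error-prone loci are a small recurrent subset: half as many artifact
  ## sites as true sites, so the same artifacts strike multiple pools
  panel[seq(1L, nrow(panel), by = 2L), , drop = FALSE]
}

#' Matrix-size / coverage performance grid
#'
#' Runs the full simulate-decode-score loop over a grid of matrix sizes
#' and allelic coverages: for each configuration, a cohort is drawn, pools
#' are simulated, decoded with [assignVariants()], and the assignments are
#' scored against the cohort's private variants, stratified by variant
#' type.
#'
#' @param sizes Vector of square matrix sizes (default `c(2, 5, 10, 24)`).
#' @param coverages Vector of allelic coverages (default
#'   `c(5, 10, 30, 100)`).
#' @param reps Replicates per grid cell (default 3).
#' @param baseConfig Template [simConfig()]; size, coverage and seed are
#'   overridden per cell.
#' @return Long-format data.frame with columns `size`, `coverage`, `rep`,
#'   `seed`, `vtype`, `tp`, `fp`, `fn`, `sensitivity`, `fdr`.
#' @export
runGrid <- function(sizes = c(2, 5, 10, 24), coverages = c(5, 10, 30, 100),
                    reps = 3, baseConfig = simConfig()) {
  out <- list()
  for (si in seq_along(sizes)) for (ci in seq_along(coverages))
    for (r in seq_len(reps)) {
      seed <- .childSeed(baseConfig@seed,
                         1000L * si + 100L * ci + r)
      cfg <- initialize(baseConfig, nRows = as.integer(sizes[si]),
                        nCols = as.integer(sizes[si]),
                        allelicCoverage = as.numeric(coverages[ci]),
                        seed = seed)
      truth <- sampleCohort(cfg)
      layout <- gridLayout(cfg@nRows, cfg@nCols)
      sim <- simulatePoolCalls(truth, layout, cfg)
      res <- assignVariants(sim$rowPools, sim$colPools, layout)
      priv <- privateVariants(singleCallerGold(truthCallSets(truth)),
                              layout)
      ev <- evaluatePinpointing(res, priv)
      agg <- ev$aggregate[ev$aggregate$stratum %in% c("SNV", "INDEL"), ]
      out[[length(out) + 1L]] <- data.frame(
        size = sizes[si], coverage = coverages[ci], rep = r, seed = seed,
        vtype = agg$stratum, tp = agg$tp, fp = agg$fp, fn = agg$fn,
        sensitivity = agg$sensitivity, fdr = agg$fdr,
        stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
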