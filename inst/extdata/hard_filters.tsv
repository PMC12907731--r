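vtype	annotation	comparator	cutoff
SNV	QD	<	2.0
SNV	FS	>	60.0
SNV	MQ	<	40.0
SNV	MQRankSum	<	-12.5
SNV	ReadPosRankSum	<	-8.0
SNV	SOR	>	3.0
INDEL	QD	<	2.0
INDEL	FS	>	200.0
INDEL	ReadPosRankSum	<	-20.0
INDEL	SOR	>	10.0
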