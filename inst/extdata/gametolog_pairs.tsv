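x_gene	y_gene
AMELX	AMELY
DDX3X	DDX3Y
EIF1AX	EIF1AY
KDM5C	KDM5D
KDM6A	UTY
NLGN4X	NLGN4Y
PCDH11X	PCDH11Y
PRKX	PRKY
RPS4X	RPS4Y1
SOX3	SRY
TBL1X	TBL1Y
TMSB4X	TMSB4Y
TXLNG	TXLNGY
USP9X	USP9Y
ZFX	ZFY
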