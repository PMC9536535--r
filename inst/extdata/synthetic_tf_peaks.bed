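chr1	1100	1300	CTCF
chr1	5400	5600	CTCF
chr1	1250	1450	EP300
chr1	5050	5250	EP300
chr1	1600	1800	FOS
chr1	5700	5900	FOS
chr1	1020	1220	POLR2A
chr1	5300	5500	POLR2A
chr1	1700	1950	REST
chr1	5100	5350	REST
chr1	1400	1600	SPI1
chr1	5550	5750	SPI1
chr1	1150	1350	STAT3
chr1	5650	5850	STAT3
chr1	1500	1700	GATA1
chr1	1300	1500	JUN
chr1	1800	1990	MYC
chr1	9000	9500	NANOG
chr1	9600	9900	SOX2
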