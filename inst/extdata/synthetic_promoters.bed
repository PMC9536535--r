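chr1	1000	2000	S100A8_prom
chr1	5000	6000	S100A9_prom
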