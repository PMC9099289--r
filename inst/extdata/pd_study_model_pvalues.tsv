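rsid	dominant_p	recessive_p	additive_p
rs12441817	0.68	0.04	0.14
rs1048943	0.13	0.14	0.071
rs762551	0.36	0.025	0.038
rs4244285	0.72	0.9	0.84
rs2070676	0.4	0.31	0.25
rs662	0.39	0.49	0.94
rs12026	0.9	0.094	0.7
rs1803274	0.76	0.87	0.75
rs4925	0.14	0.56	0.14
rs156697	0.049	0.16	0.033
rs1695	0.67	0.72	0.63
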