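enzyme_class	pattern	control_carriers	case_carriers
CYP	2/2/2/1/1	14	4
CYP	2/2/2/-/1	27	12
CYP	2/-/2/-/1	34	15
CYP	2/-/-/-/1	40	18
esterase	1/1/1	21	28
esterase	1/1/-	28	36
GST	P/N/1/2/1	17	5
GST	P/N/-/2/1	34	17
GST	P/N/-/2/-	57	32
GST	-/N/-/2/-	117	89
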