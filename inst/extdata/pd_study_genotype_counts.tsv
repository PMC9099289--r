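rsid	group	g1	g2	g3
rs12441817	control	138	242	119
rs12441817	case	150	280	97
rs1048943	control	288	174	37
rs1048943	case	328	177	22
rs762551	control	66	232	201
rs762551	case	77	277	173
rs4244285	control	213	226	60
rs4244285	case	223	246	58
rs2070676	control	12	157	330
rs2070676	case	9	152	366
rs662	control	60	235	204
rs662	case	75	225	227
rs12026	control	329	153	17
rs12026	case	347	170	10
rs1803274	control	393	101	5
rs1803274	case	417	105	5
GSTM1	control	279	220	NA
GSTM1	case	270	257	NA
GSTT1	control	258	241	NA
GSTT1	case	295	232	NA
rs4925	control	343	141	15
rs4925	case	380	132	15
rs156697	control	263	192	44
rs156697	case	305	189	33
rs1695	control	320	159	20
rs1695	case	333	174	20
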