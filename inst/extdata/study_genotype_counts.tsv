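study	case_n44	case_n45	case_n55	case_n4555	control_n44	control_n45	control_n55	control_n4555
Cohort1	761	666	148	814	816	679	145	824
Cohort2	245	251	64	315	268	248	51	299
Zhu	180	175	36	211	206	198	28	226
Dai	1092	406	21	427	1181	395	24	419
Wirth	85	NA	NA	144	81	NA	NA	131
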