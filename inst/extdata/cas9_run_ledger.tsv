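group	method	start_note	time_per_run_ns	n_runs
G1	cMD	crystal structure 5F9R, ntDNA removed	2500	2
G2	cMD	crystal structure 5F9R, ntDNA removed, Mg at HNH	1000	1
G3	aMD_dihedral	extracted from G1	650	2
G4	aMD_dual	extracted from G1	1000	2
G5	tMD	extracted from G1/G2	100	2
G6	cMD	extracted from G5, Mg at HNH	800	2
G7	cMD	extracted from G6, Mg moved to bulk	800	2
G8.1	cMDens	extracted from G1/G2, Mg at HNH	500	10
G8.2	cMDens	extracted from G8.1	500	10
G8.3	cMDens	extracted from G8.2	500	10
G8.4	cMDens	extracted from G8.3	500	10
G9	cMD	extracted from G6/G8.4, D839A mutant	850	2
G10	cMD	crystal structure 5F9R, with ntDNA	1000	2
G10	cMD	crystal structure 5F9R, with ntDNA	1500	2
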