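# Per-sample sequencing coverage summaries for the 12 individually sequenced
# base-population females. Nuclear and Wolbachia mean depths and clade labels
# are the published per-sample values; wolbachia_breadth and mean_depth_mtdna
# are SYNTHETIC placeholders (plausible magnitudes only; per-sample breadth
# and mtDNA depth were not published).
sample_id	wolbachia_clade	mtdna_clade	mean_depth_wolbachia	mean_depth_nuclear	mean_depth_mtdna	wolbachia_breadth	group
w2	VI	VI	209.91	17.07	2610.4	0.993	infected
w4	n.i.	VI	3.44	24.76	3105.2	0.081	uninfected
w5	n.i.	III	2.88	24.01	2240.9	0.064	uninfected
w6	VI	VI	139.10	16.69	1892.7	0.991	infected
w7	n.i.	VI	2.71	20.90	2471.3	0.055	uninfected
w12	n.i.	III	3.23	24.94	3869.5	0.072	uninfected
w13	n.i.	VI	3.75	33.20	2035.6	0.088	uninfected
w14	I	I	272.23	39.89	6714.8	0.996	infected
w15	n.i.	I	2.67	25.66	1678.0	0.049	uninfected
w16	n.i.	V	2.727	22.56	3590.1	0.066	uninfected
w18	V	V	138.56	21.57	1285.0	0.989	infected
w19	n.i.	I	3.23	32.57	2948.7	0.061	uninfected
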