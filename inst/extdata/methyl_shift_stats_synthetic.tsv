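residue_type	methyl_site	mean_shift_h	sd_shift_h	mean_shift_c	sd_shift_c
Ala	B	1.39	0.26	19.0	1.8
Ile	D1	0.68	0.28	13.4	1.7
Ile	G2	0.78	0.26	17.4	1.4
Leu	D1	0.76	0.27	24.7	1.6
Leu	D2	0.73	0.27	24.1	1.7
Val	G1	0.83	0.26	21.5	1.4
Val	G2	0.80	0.27	21.3	1.6
Thr	G2	1.14	0.22	21.6	1.1
Met	E	1.86	0.29	17.2	1.3
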