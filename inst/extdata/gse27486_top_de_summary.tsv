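rna	mean_case	sd_case	mean_control	sd_control	fold_change_printed
miRPlus-E1016	211.82	129.47	133.2	53.13	1.59
SNORD2	277.69	156.92	185.25	36.39	1.50
SNORD44	132.65	65.03	91.02	17.84	1.46
SNORD3	602.26	261.49	415.53	104.4	1.45
RNU5	750.37	310.9	521.01	111.97	1.44
RNU6-1	552.41	184.89	390.61	118.08	1.41
RNU6-1/RNU6-2	4037.13	1552.97	2878.75	896.93	1.40
miRPlus-C1110	312.42	62.17	224.99	50.54	1.39
miRPlus-E1258	86.75	20.49	64.07	11.77	1.35
miR-720	340.15	119.55	252.95	74.57	1.34
miR-1290	171.55	50.99	128.19	32.76	1.34
SNORD13	513.58	204.28	384.05	88.93	1.34
miR-144	143.57	72.96	267.88	119.29	0.54
let-7f	172.56	96.41	312.48	150.58	0.55
miR-15a	1067.1	500.02	1899.57	859.99	0.56
miR-20a	315.49	215.14	560.07	295.46	0.56
miR-18a	103.44	62.86	175.58	100.54	0.59
miR-1976	1141.76	601.13	1936.79	853.76	0.59
miR-93	585.97	374.69	980.62	477.89	0.60
miR-20b	50.43	24.24	83.2	43.62	0.61
miR-320c	207.32	83.05	339.03	172.55	0.61
miR-17	604.37	343.17	975.14	443.34	0.62
miR-652	126.41	53.51	202.94	75.64	0.62
miR-18b	44.08	24.7	69.15	38.45	0.64
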