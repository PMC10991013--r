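item_id	item_type	expected	freq0	freq1	freq2	printed_ratio	printed_mean	printed_variance	printed_e
i1	no-turn	0.50	0	2	77	3.94	1.97	0.02	0.19
i2	no-turn	0.36	0	4	75	5.42	1.95	0.05	0.57
i3	no-turn	0.21	1	0	78	9.38	1.97	0.05	0.66
i4	single-turn	0.30	0	0	79	6.67	2.00	0.00	0.00
i5	single-turn	0.36	4	5	70	5.11	1.84	0.24	0.13
i6	single-turn	0.29	0	15	64	6.24	1.81	0.16	0.21
i7	double-turn	0.21	8	16	55	7.57	1.59	0.45	0.53
i8	double-turn	0.43	20	10	49	3.19	1.37	0.75	0.33
i9	double-turn	0.19	47	24	8	2.68	0.51	0.46	0.46
i10	full-turn	0.80	9	19	51	1.91	1.53	0.48	0.39
i11	full-turn	0.62	1	45	33	2.27	1.41	0.27	0.44
i12	full-turn	0.50	8	25	46	2.96	1.48	0.46	0.31
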