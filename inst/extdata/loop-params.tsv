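type	size	dG37	dS
hairpin	3	5.4	-0.017411
hairpin	4	5.6	-0.018056
hairpin	5	5.7	-0.018378
hairpin	6	5.4	-0.017411
hairpin	7	6	-0.019345
hairpin	8	5.5	-0.017733
hairpin	9	6.4	-0.020635
hairpin	10	6.51	-0.02099
hairpin	11	6.62	-0.021345
hairpin	12	6.71	-0.021635
hairpin	13	6.8	-0.021925
hairpin	14	6.88	-0.022183
hairpin	15	6.95	-0.022409
hairpin	16	7.02	-0.022634
hairpin	17	7.09	-0.02286
hairpin	18	7.15	-0.023053
hairpin	19	7.21	-0.023247
hairpin	20	7.26	-0.023408
hairpin	21	7.31	-0.023569
hairpin	22	7.36	-0.02373
hairpin	23	7.41	-0.023892
hairpin	24	7.46	-0.024053
hairpin	25	7.5	-0.024182
hairpin	26	7.54	-0.024311
hairpin	27	7.59	-0.024472
hairpin	28	7.62	-0.024569
hairpin	29	7.66	-0.024698
hairpin	30	7.7	-0.024827
bulge	1	3.8	-0.012252
bulge	2	2.8	-0.009028
bulge	3	3.2	-0.010318
bulge	4	3.6	-0.011607
bulge	5	4	-0.012897
bulge	6	4.4	-0.014187
bulge	7	4.57	-0.014735
bulge	8	4.71	-0.015186
bulge	9	4.84	-0.015605
bulge	10	4.95	-0.01596
bulge	11	5.05	-0.016282
bulge	12	5.15	-0.016605
bulge	13	5.23	-0.016863
bulge	14	5.31	-0.017121
bulge	15	5.39	-0.017379
bulge	16	5.46	-0.017604
bulge	17	5.52	-0.017798
bulge	18	5.59	-0.018024
bulge	19	5.64	-0.018185
bulge	20	5.7	-0.018378
bulge	21	5.75	-0.018539
bulge	22	5.8	-0.018701
bulge	23	5.85	-0.018862
bulge	24	5.9	-0.019023
bulge	25	5.94	-0.019152
bulge	26	5.98	-0.019281
bulge	27	6.02	-0.01941
bulge	28	6.06	-0.019539
bulge	29	6.1	-0.019668
bulge	30	6.14	-0.019797
internal	2	1	-0.003224
internal	3	1.8	-0.005804
internal	4	2	-0.006448
internal	5	2.2	-0.007093
internal	6	2.5	-0.008061
internal	7	2.67	-0.008609
internal	8	2.81	-0.00906
internal	9	2.94	-0.009479
internal	10	3.05	-0.009834
internal	11	3.15	-0.010156
internal	12	3.25	-0.010479
internal	13	3.33	-0.010737
internal	14	3.41	-0.010995
internal	15	3.49	-0.011253
internal	16	3.56	-0.011478
internal	17	3.62	-0.011672
internal	18	3.69	-0.011897
internal	19	3.74	-0.012059
internal	20	3.8	-0.012252
internal	21	3.85	-0.012413
internal	22	3.9	-0.012575
internal	23	3.95	-0.012736
internal	24	4	-0.012897
internal	25	4.04	-0.013026
internal	26	4.08	-0.013155
internal	27	4.12	-0.013284
internal	28	4.16	-0.013413
internal	29	4.2	-0.013542
internal	30	4.24	-0.013671
multiloop_base	NA	3.4	-0.010962
multiloop_branch	NA	0.4	-0.00129
multiloop_unpaired	NA	0.1	-0.000322
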