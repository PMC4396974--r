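cohort	sample	method	mad	signal	snr	region
melanoma_pdx	T98	offtarget	0.206	0.722	3.50	chr6p
melanoma_pdx	T98	snp6	0.547	0.721	1.32	chr6p
melanoma_pdx	T99	offtarget	0.241	0.344	1.43	chr16
melanoma_pdx	T99	snp6	0.610	0.302	0.50	chr16
melanoma_pdx	T100	offtarget	0.225	0.618	2.75	chr1q
melanoma_pdx	T100	snp6	0.680	0.649	0.95	chr1q
melanoma_pdx	T101	offtarget	0.252	0.996	3.95	chr1q
melanoma_pdx	T101	snp6	0.927	0.829	0.89	chr1q
melanoma_pdx	T102	offtarget	0.248	0.592	2.39	chr8q
melanoma_pdx	T102	snp6	0.753	0.617	0.82	chr8q
melanoma_pdx	T103	offtarget	0.237	0.978	4.13	chr2q
melanoma_pdx	T103	snp6	0.516	0.931	1.80	chr2q
mouse_sclc	T21	offtarget	0.351	0.585	1.67	chr2:141-182Mb
mouse_sclc	T21	arraycgh	0.246	0.49	1.99	chr2:141-182Mb
mouse_sclc	T22	offtarget	0.341	0.532	1.56	chr2:147-182Mb
mouse_sclc	T22	arraycgh	0.276	0.493	1.79	chr2:147-182Mb
mouse_sclc	T23	offtarget	0.479	-0.626	1.31	chr7:116-153Mb
mouse_sclc	T23	arraycgh	0.219	-0.443	2.02	chr7:116-153Mb
mouse_sclc	T24	offtarget	0.580	1.115	1.92	chr10:80-108Mb
mouse_sclc	T24	arraycgh	0.274	0.737	2.69	chr10:80-108Mb
mouse_mammary	T60	offtarget	0.262	0.523	2.00	chr6:52-120Mb
mouse_mammary	T60	lcwgs	0.176	0.501	2.85	chr6:52-120Mb
mouse_mammary	T60	ontarget	0.159	0.467	2.94	chr6:52-120Mb
mouse_mammary	T56	offtarget	0.250	0.494	1.98	chr16:12-25Mb
mouse_mammary	T56	lcwgs	0.170	0.513	3.02	chr16:12-25Mb
mouse_mammary	T56	ontarget	0.172	0.568	3.30	chr16:12-25Mb
mouse_mammary	T20	offtarget	0.314	1.099	3.50	chr8:7-16Mb
mouse_mammary	T20	lcwgs	0.271	0.978	3.61	chr8:7-16Mb
mouse_mammary	T20	ontarget	0.653	1.135	1.74	chr8:7-16Mb
mouse_mammary	T62	offtarget	0.265	0.421	1.59	chr8:3-47Mb
mouse_mammary	T62	lcwgs	0.185	0.403	2.18	chr8:3-47Mb
mouse_mammary	T62	ontarget	0.160	0.376	2.35	chr8:3-47Mb
mouse_mammary	T19	offtarget	0.252	1.314	5.21	chr8:22-39Mb
mouse_mammary	T19	lcwgs	0.163	1.272	7.80	chr8:22-39Mb
mouse_mammary	T19	ontarget	0.591	1.24	2.10	chr8:22-39Mb
mouse_mammary	T2	offtarget	0.395	0.303	0.77	chr5:38-152Mb
mouse_mammary	T2	lcwgs	0.255	0.335	1.31	chr5:38-152Mb
mouse_mammary	T2	ontarget	0.230	0.344	1.50	chr5:38-152Mb
mouse_mammary	T3	offtarget	0.293	0.401	1.37	chr15:87-104Mb
mouse_mammary	T3	lcwgs	0.212	0.361	1.70	chr15:87-104Mb
mouse_mammary	T3	ontarget	0.181	0.286	1.58	chr15:87-104Mb
mouse_mammary	T7	offtarget	0.597	0.395	0.66	chr6
mouse_mammary	T7	lcwgs	0.538	0.398	0.74	chr6
mouse_mammary	T7	ontarget	0.330	0.371	1.12	chr6
mouse_mammary	T50	offtarget	0.262	0.477	1.82	chr5
mouse_mammary	T50	lcwgs	0.193	0.486	2.52	chr5
mouse_mammary	T50	ontarget	0.175	0.462	2.64	chr5
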