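rsid	chromosome	position	cytoband	gene	functional_region	risk_allele	ref_allele	or_value	ci_low	ci_high	p_value	afr_freq_1kg	afr_n_1kg	afr_freq_gnomad	afr_n_gnomad	eur_freq_1kg	eur_n_1kg	eur_freq_gnomad	eur_n_gnomad
rs000001	5	63383651				G	T	1.4824401139090113				0.60211800302571861	661	0.59531250000000002	8000	0.59228441754916794	661	0.57350000000000001	8000
rs000002	5	136767673				G	C	1.2301126105574647				0.58925869894099847	661	0.59418749999999998	8000	0.56883509833585477	661	0.57637499999999997	8000
rs000003	5	213057331				C	T	1.133853566054446				0.57413010590015123	661	0.59368750000000003	8000	0.60136157337367624	661	0.56937499999999996	8000
rs000004	21	116872805				G	C	1.0726107984109479				0.95839636913767023	661	0.95506250000000004	8000	0.94856278366111957	661	0.94568750000000001	8000
rs000005	14	169695747				C	T	1.3599489733599852				0.54387291981845687	661	0.55900000000000005	8000	0.5431164901664145	661	0.53106249999999999	8000
rs000006	12	73182199				A	T	1.4743022145202236				0.9818456883509834	661	0.97875000000000001	8000	0.92360060514372166	661	0.91756249999999995	8000
rs000007	16	67802896				T	C	1.5931704859394207				0.73751891074130105	661	0.70531250000000001	8000	0.65885022692889561	661	0.65300000000000002	8000
rs000008	1	167113659				G	C	1.4656777841452766				0.29425113464447805	661	0.3041875	8000	0.30937972768532529	661	0.3188125	8000
rs000009	14	45693483				G	A	1.2853381230553229				0.34266263237518912	661	0.34899999999999998	8000	0.36686838124054461	661	0.36631249999999999	8000
rs000010	22	120999864				G	A	1.1471661581514732				0.25189107413010592	661	0.25062499999999999	8000	0.18835098335854766	661	0.21087500000000001	8000
rs000011	6	80215795				A	T	1				0.57261724659606661	661	0.57750000000000001	8000	0.5363086232980333	661	0.54774999999999996	8000
rs000012	7	60473745				G	A	1				0.49167927382753401	661	0.50806249999999997	8000	0.51437216338880487	661	0.50524999999999998	8000
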