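mirna	sequence	cy_tpm	yk_tpm	fold_change	p_value	fdr	direction	n_targets
bta-novel-miR-13	ACCTCCCGTGGAGCAGAAGGGCA	21.90231	10.62615	2.061171	3.46E-06	9.83E-05	UP	3413
bta-novel-miR-19	ACTTTTGCCCCTAGTAACGGACT	6.102984	1	6.102984	0.000796	0.008075	UP	144
bta-novel-miR-27	ATCTGTAGTCTCGGCGTCGCACT	8.335362	1	8.335362	7.56E-05	0.001535	UP	871
bta-novel-miR-33	CACCTAGCACTCGCTCGCACC	14.32744	6.812611	2.103076	9.39E-05	0.001213	UP	125
bta-novel-miR-65	GATATTGACATCTCTGGACCC	8.224455	1	8.224455	7.56E-05	0.001535	UP	40
bta-novel-miR-77	GGGCATACTTGTAGACCTTGCC	19.83946	7.238399	2.740862	1.86E-06	6.61E-05	UP	424
bta-novel-miR-118	TCTTAAGATTTGGTGCAATATG	6.02061	1	6.0206	0.000796	0.008075	UP	35
bta-novel-miR-160	TTCTCTTCAGATCGTATAAATC	8.165835	1	8.165835	7.56E-05	0.001535	UP	130
bta-novel-miR-40	CCCGCGAGGGGGCGGGGC	1	57.18054	0.017488	1.29E-07	6.09E-06	DOWN	994
bta-novel-miR-96	TACTGTGCCTTGAATGGG	1	30.7545	0.032516	0.000501	0.005469	DOWN	363
bta-novel-miR-128	TGATTGGTACTTCTTAGAGTGGA	34.147893	325.4347	0.10493	2.39E-21	3.39E-19	DOWN	122
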