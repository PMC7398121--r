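gene	cdna	protein	variant_type	splice_region	native_loss_cat	gain_cat	aberration	transcripts	allele_specific	nmd_inhibitor	full_length_alt	percent_wt	assay_source	prior	lr_tumor	lr_segregation	lr_functional	insight_class	contributes	study_source	notes
MLH1	c.299G>C	p.(Arg100Pro)	missense	0			0		0	1		8	CIMRA_calibrated	0.1	8	15	10	5	no	this_study	LRs reconstructed
MLH1	c.793C>T	p.(Arg265Cys)	missense	1			1	r.791_884del	1	1	no	15	CIMRA_calibrated	0.1				5	yes	this_study	
MLH1	c.923A>C	p.(His308Pro)	missense	0			1	r.[791_1038del, 923a>c]	1	1	yes	10	CIMRA_calibrated	0.1	8	15	10	5	no	this_study	LRs reconstructed
MLH1	c.1136A>G	p.(Tyr379Cys)	missense	0			0		0	1		95	CIMRA_calibrated	0.1	0.1	0.1	0.5	1	no	this_study	LRs reconstructed
MLH1	c.1166G>A	p.(Arg389Gln)	missense	0			1	r.[1039_1409del, 1166g>a]	1	1	yes	50	CIMRA_calibrated	0.1				3	no	this_study	
MLH1	c.1652A>G	p.(Asn551Ser)	missense	0			0		0	1		90	CIMRA_calibrated	0.1	0.1	0.1	0.5	1	no	this_study	LRs reconstructed
MSH2	c.944G>T	p.(Gly315Val)	missense	0			0		0	1		88	CIMRA_calibrated	0.1	0.1	0.1	0.5	1	no	this_study	LRs reconstructed
MSH2	c.1661G>A	p.(Ser554Asn)	missense	1			1	r.1511_1661del	1	1	no	55	CIMRA_calibrated	0.1				5	yes	this_study	
MSH2	c.2075G>T	p.(Gly692Val)	missense	0			0		0	1		5	CIMRA_calibrated	0.1	8	15	10	5	no	this_study	LRs reconstructed
MSH2	c.2714C>G	p.(Thr905Arg)	missense	0			0		0	1		102	CIMRA_calibrated	0.1	0.1	0.1	0.5	1	no	this_study	LRs reconstructed
MSH6	c.2314C>T	p.(Arg772Trp)	missense	0			1	r.[628_3172del, 2314c>u]	1	1	yes	5	CIMRA_calibrated	0.1	8	15	10	5	no	this_study	LRs reconstructed
MSH6	c.3469G>A	p.(Gly1157Ser)	missense	0			0		0	1		40	CIMRA_calibrated	0.1	20	15		4	no	this_study	LRs reconstructed
MLH1	c.438A>G		silent	0			0		0	1				0.1				2	yes	this_study	
MSH2	c.1275A>G		silent	1			1	r.[1229_1276del, 1275a>g]	1	1	yes			0.1				3	no	this_study	
MSH2	c.1344C>T		silent	0			0		0	1				0.1				2	yes	this_study	
MSH2	c.2154A>G		silent	0			0		0	1				0.1				2	yes	this_study	
MSH6	c.3246G>T		silent	0			0		0	1				0.1	0.05	0.1		1	no	this_study	LRs reconstructed
MLH1	c.117-2A>G		splice_site	1			1	r.117_121del	0	1	na			0.1	30	40		5	no	this_study	LRs reconstructed
MLH1	c.589-2A>C		splice_site	1			1	r.589_677del	0	1	na			0.1				4	no	this_study	
MLH1	c.790+2T>A		splice_site	1			1	r.678_790del	0	1	na			0.1	30	40		5	no	this_study	LRs reconstructed
MLH1	c.454-13A>G		intronic	1			1	r.454_545del	0	1	na			0.1				4	yes	this_study	
MSH2	c.1276+11A>G		intronic	0			0		0	1				0.1				2	yes	this_study	
MSH2	c.1511-9A>G		intronic	1			0		0	1				0.1				2	yes	this_study	
MSH2	c.1661+5G>C		intronic	1			1	r.1511_1661del	0	1	na			0.1				4	yes	this_study	
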