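name	species	family	subfamily	cyp_type	status	clan	cluster	parent_gene
CYP1A1	Hosa	1	1A	D	functional	2		
CYP1A2	Hosa	1	1A	D	functional	2		
CYP1B1	Hosa	1	1B	D	functional	2		
CYP2A6	Hosa	2	2A	D	functional	2	cyp2_chr19q	
CYP2A7	Hosa	2	2A	D	functional	2	cyp2_chr19q	
CYP2A13	Hosa	2	2A	D	functional	2	cyp2_chr19q	
CYP2B6	Hosa	2	2B	D	functional	2	cyp2_chr19q	
CYP2C8	Hosa	2	2C	D	functional	2	cyp2c_chr10q	
CYP2C9	Hosa	2	2C	D	functional	2	cyp2c_chr10q	
CYP2C18	Hosa	2	2C	D	functional	2	cyp2c_chr10q	
CYP2C19	Hosa	2	2C	D	functional	2	cyp2c_chr10q	
CYP2D6	Hosa	2	2D	D	functional	2		
CYP2E1	Hosa	2	2E	D	functional	2		
CYP2F1	Hosa	2	2F	D	functional	2	cyp2_chr19q	
CYP2J2	Hosa	2	2J	D	functional	2		
CYP2R1	Hosa	2	2R	D	functional	2		
CYP2S1	Hosa	2	2S	D	functional	2	cyp2_chr19q	
CYP2U1	Hosa	2	2U	D	functional	2		
CYP2W1	Hosa	2	2W	D	functional	2		
CYP3A4	Hosa	3	3A	D	functional	3	cyp3a_chr7q	
CYP3A5	Hosa	3	3A	D	functional	3	cyp3a_chr7q	
CYP3A7	Hosa	3	3A	D	functional	3	cyp3a_chr7q	
CYP3A43	Hosa	3	3A	D	functional	3	cyp3a_chr7q	
CYP4A11	Hosa	4	4A	D	functional	4	cyp4_chr1p	
CYP4A20	Hosa	4	4A	D	functional	4	cyp4_chr1p	
CYP4A22	Hosa	4	4A	D	functional	4	cyp4_chr1p	
CYP4B1	Hosa	4	4B	D	functional	4	cyp4_chr1p	
CYP4F2	Hosa	4	4F	D	functional	4	cyp4f_chr19p	
CYP4F3	Hosa	4	4F	D	functional	4	cyp4f_chr19p	
CYP4F8	Hosa	4	4F	D	functional	4	cyp4f_chr19p	
CYP4F11	Hosa	4	4F	D	functional	4	cyp4f_chr19p	
CYP4F12	Hosa	4	4F	D	functional	4	cyp4f_chr19p	
CYP4F22	Hosa	4	4F	D	functional	4		
CYP4V2	Hosa	4	4V	D	functional	4		
CYP4X1	Hosa	4	4X	D	functional	4	cyp4_chr1p	
CYP5A1	Hosa	5	5A	B	functional	3		
CYP7A1	Hosa	7	7A	B	functional	7		
CYP7B1	Hosa	7	7B	B	functional	7		
CYP8A1	Hosa	8	8A	B	functional	7		
CYP8B1	Hosa	8	8B	B	functional	7		
CYP11A1	Hosa	11	11A	B	functional	mito		
CYP11B1	Hosa	11	11B	B	functional	mito		
CYP11B2	Hosa	11	11B	B	functional	mito		
CYP17A1	Hosa	17	17A	B	functional	2		
CYP19A1	Hosa	19	19A	B	functional	19		
CYP20A1	Hosa	20	20A	B	functional	20		
CYP21A2	Hosa	21	21A	B	functional	2		
CYP24A1	Hosa	24	24A	B	functional	mito		
CYP26A1	Hosa	26	26A	B	functional	26		
CYP26B1	Hosa	26	26B	B	functional	26		
CYP26C1	Hosa	26	26C	B	functional	26		
CYP27A1	Hosa	27	27A	B	functional	mito		
CYP27B1	Hosa	27	27B	B	functional	mito		
CYP27C1	Hosa	27	27C	B	functional	mito		
CYP39A1	Hosa	39	39A	B	functional	7		
CYP46A1	Hosa	46	46A	B	functional	46		
CYP51A1	Hosa	51	51A	B	functional	51		
CYP1D1P	Hosa	1	1D	D	pseudogene	2		CYP1D1
CYP2A7P1	Hosa	2	2A	D	pseudogene	2	cyp2_chr19q	CYP2A7
CYP2B7P1	Hosa	2	2B	D	pseudogene	2	cyp2_chr19q	CYP2B7
CYP2D7P1	Hosa	2	2D	D	pseudogene	2		CYP2D7
CYP2D8P1	Hosa	2	2D	D	pseudogene	2		CYP2D8
CYP2F1P	Hosa	2	2F	D	pseudogene	2	cyp2_chr19q	CYP2F1
CYP2G1P	Hosa	2	2G	D	pseudogene	2	cyp2_chr19q	CYP2G1
CYP2G2P	Hosa	2	2G	D	pseudogene	2	cyp2_chr19q	CYP2G2
CYP2T2P	Hosa	2	2T	D	pseudogene	2	cyp2_chr19q	CYP2T2
CYP2T3P	Hosa	2	2T	D	pseudogene	2		CYP2T3
CYP4F9P	Hosa	4	4F	D	pseudogene	4	cyp4f_chr19p	CYP4F9
CYP4F23P	Hosa	4	4F	D	pseudogene	4		CYP4F23
CYP4F24P	Hosa	4	4F	D	pseudogene	4	cyp4f_chr19p	CYP4F24
CYP4Z2P	Hosa	4	4Z	D	pseudogene	4	cyp4_chr1p	CYP4Z2
CYP21A1P	Hosa	21	21A	B	pseudogene	2		CYP21A2
CYP51P1	Hosa	51	51P	B	pseudogene	51		CYP51A1
CYP51P2	Hosa	51	51P	B	pseudogene	51		CYP51A1
CYP3A51P	Hosa	3	3A	D	pseudogene	3	cyp3a_chr7q	
CYP3A52P	Hosa	3	3A	D	pseudogene	3	cyp3a_chr7q	
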