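family	ethnicity	gene	position	transcript	hgvs_c	hgvs_p	variation	protein_function	cadd	exac_af_e6	omim
PKMR30	Punjabi	DGCR8	Chr22:20073866G>A	NM_022720.6	c.380G>A	p.(Ser127Asn)	Missense	miRNA biogenesis	22.9	8.248	609030
PKMR30	Punjabi	FNIP2	Chr4:159812659G>T	NM_020840.1	c.3011G>T	p.(Trp1004Leu)	Missense	Folliculin-interacting protein	23.6	967.4	612768
PKMR30	Punjabi	GSTCD	Chr4:106640368A>G	NM_001031720.3	c.578A>G	p.(Asp193Gly)	Missense	Glutathione S-transferase	29.8	49.49	615912
PKMR30	Punjabi	TOP3B	Chr22:22318366G>T	NM_003935.4	c.1133C>A	p.(Pro378Gln)	Missense	Topoisomerase	27.6	0	603582
PKMR51b	Pathan	CPT1B	Chr22:51008816C>T	NM_152245.2	c.2048G>A	p.(Arg683His)	Missense	Acetyltransferase	35.0	164.2	601987
PKMR51b	Pathan	PHACTR1	Chr6:13228209C>T	NM_030948.2	c.1148C>T	p.(Ser383Leu)	Missense	Phosphatase and actin regulator	23.2	0	608723
PKMR52	Pathan	STX19	Chr3:93733695A>G	NM_001001850.2	c.419T>C	p.(Met140Thr)	Missense	SNARE protein	24.1	82.42	NA
PKMR52	Pathan	TBC1D23	Chr3:100035033T>G	NM_001199198.2	c.1687+2T>G	p.(Asp563Glyfs*33)	Aberrant splicing	Rab GTPase activator	NA	0	NA
PKMR65	Punjabi	DNAJC2	Chr7:102956464A>G	NM_014377.1	c.1499T>C	p.(Ile500Thr)	Missense	Phosphoprotein	29.7	75.31	605502
PKMR65	Punjabi	LINGO1	Chr15:77907386T>C	NM_032808.6	c.863A>G	p.(Tyr288Cys)	Missense	Cell signaling	24.6	8.285	609791
PKMR65	Punjabi	VAPA	Chr18:9945020A>G	NM_003574.5	c.517A>G	p.(Arg173Gly)	Missense	Membrane protein	21.6	0	605703
PKMR120	Punjabi	LRRC6	Chr8:133669098A>C	NM_012472.4	c.234T>G	p.(Ile78Met)	Missense	Receptor extracellular matrix protein	24.7	185.7	614930
PKMR120	Punjabi	SLC45A4	Chr8:142228631C>T	NM_001080431.2	c.955G>A	p.(Asp319Asn)	Missense	Solute carrier	24.8	375.2	NA
PKMR131	Punjabi	ESYT3	Chr3:138191644C>T	NM_031913.3	c.2180C>T	p.(Ser727Leu)	Missense	Extended synaptotagmin	34	124.3	616692
PKMR131	Punjabi	CCT6B	Chr17:33285649C>A	NM_001193529.2	c.266G>T	p.(Gly89Val)	Missense	Chaperonin-containing T-complex	31	0	610730
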