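family	ethnicity	gene	position	transcript	hgvs_c	hgvs_p	variation	protein_function	cadd	exac_af_e6	omim
PKMR61b	Punjabi	TMEM67	Chr8:94827616G>A	NM_153704.5	c.2848G>A	p.(Val950Met)	Missense	Centriole migration to the apical membrane	32.0	8.516	609884
PKMR61b	Punjabi	FGFR1	Chr8:38271255G>A	NM_023110.2	c.2360C>T	p.(Thr787Met)	Missense	Fibroblast growth factor receptor	29.2	126.8	136350
PKMR69	Punjabi	FRAS1	Chr4:79443907G>A	NM_025074.6	c.10753G>A	p.(Ala3585Thr)	Missense	Extracellular matrix protein	24.4	27.21	607830
PKMR69	Punjabi	EXOSC8	Chr13:37580059C>T	NM_181503.2	c.241C>T	p.(Pro81Ser)	Missense	Exosome component	28.2	173.6	606019
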