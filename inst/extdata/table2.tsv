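family	ethnicity	gene	position	transcript	hgvs_c	hgvs_p	variation	protein_function	cadd	exac_af_e6
PKMR24	Punjabi	ZSCAN25	Chr7:99219114A>G	NM_145115.2	c.506A>G	p.(Glu169Gly)	Missense	Zinc finger protein nucleic acid binding	26.5	0
PKMR33	Punjabi	DPH1	Chr17:1944817C>T	NM_001383.3	c.1144C>T	p.(Pro382Ser)	Missense	Diphthamide biosynthesis	32	8.515
PKMR40	Pathan	DCTN2	Chr12:57929561T>G	NM_001261412.1	c.173A>C	p.(Lys58Thr)	Missense	Structural protein	26.8	8.484
PKMR43	Pathan	METTL5	Chr2:170677663_64delTC	NM_014168.3	c.344_345delGA	p.(Arg115Asnfs*19)	Frameshift	Methyl transferase	NA	0
PKMR45	Pathan	TANGO2	Chr22:20041047G>T	NM_152906.5	c.353G>T	p.(Gly118Val)	Missense	Transport and Golgi organization	29.4	0
PKMR64	Punjabi	CAPN12	Chr19:39230761_62delTT	NM_144691.4	c.658_659delAA	p.(Asn220Glnfs*25)	Frameshift	Cystine protease	NA	795.1
PKMR66	Punjabi	TBC1D8	Chr2:101652537G>A	NM_001102426.1	c.1501C>T	p.(Leu501Phe)	Missense	G-protein modulator	31.0	99.37
PKMR67	Punjabi	MSS51	Chr10:75187870G>A	NM_001024593.1	c.173C>T	p.(Ser58Leu)	Missense	Zinc finger transcription factor	33.0	140.1
PKMR72	Punjabi	MDGA2	Chr14:47343402T>C	NM_001113498.2	c.2232A>G	p.(Arg744Arg)	Aberrant Splicing	GPI anchor	NA	52.83
PKMR98	Punjabi	FMOD	Chr1:203316893C>T	NM_002023.4	c.506G>A	p.(Arg169Gln)	Missense	Receptor	23.3	296.6
PKMR118	Punjabi	C22orf31	Chr22:29454885C>G	NM_015370.1	c.718G>C	p.(Gly240Arg)	Missense	Unknown	28.6	0
PKMR142	Punjabi	SMARCA1	ChrX:128657269C>T	NM_139035.2	c.79G>A	p.(Glu27Lys)	Missense	Component of NURF complex	22.1	35.55
PKMR153	Punjabi	GPAA1	Chr8:145138854G>C	NM_003801.3	c.527G>C	p.(Trp176Ser)	Missense	Glycosylphosphatidylinositol	27.6	16.58
PKMR155	Kashmiri	OR2A12	Chr7:143792562G>A	NM_001004135.1	c.362G>A	p.(Arg121Gln)	Missense	Olfactory receptor	24.1	16.57
PKMR159	Punjabi	AACS	Chr12:125612785A>G	NM_023928.3	c.1388A>G	p.(Asn463Ser)	Missense	Acetoacetyl-Co synthetase	21.2	82.95
PKMR159	Punjabi	AACS	Chr12:125621351C>T	NM_023928.3	c.1822C>T	p.(Arg608Cys)	Missense	Acetoacetyl-Co synthetase	34.0	198.1
PKMR164	Punjabi	GGN	Chr19:38877823G>A	NM_152657.3	c.79C>T	p.(Arg27Cys)	Missense	Germ cell specific gene	25.9	362.3
PKMR174	Siraki	MEGF9	Chr9:123421769C>T	NM_001080497.2	c.686G>A	p.(Gly229Asp)	Missense	Receptor	26.8	59.54
PKMR195	Siraki	WFDC1	Chr16:84360517G>A	NM_021197.3	c.634G>A	p.(Gly212Arg)	Missense	Protease inhibitor	24.2	65.89
PKMR198	Punjabi	METTL4	Chr18:2554909G>T	NM_022840.4	c.588C>A	p.(Cys196*)	Nonsense	Methyl transferase	NA	41.19
PKMR200	Siraiki	UBE2J2	Chr1:1203295_96delTT	NM_194315.1	c.77_78delAA	p.(Lys26Argfs*30)	Frameshift	Ubiquitin protein ligase	NA	0
PKMR206	Siraiki	CCDC82	Chr11:96117539delC	NM_024725.3	c.373delG	p.(Asp125Ilefs*6)	Frameshift	Unknown	NA	0
PKMR213	Siraiki Baloch	TMEM222	Chr1:27657230G>A	NM_032125.2	c.214G>A	p.(Gly72Ser)	Missense	Transmembrane protein	34.0	8.237
PKMR215	Siraiki	PUS7	chr7:105148870_71delTG	NM_019042.3	c.89_90delCA	p.(Thr30Lysfs*20)	Frameshift	Pseudouridylate synthetase	NA	8.237
PKMR258	Punjabi	AREL1	Chr14:75150203G>A	NM_001039479.1	c.277C>T	p.(His93Tyr)	Missense	Ubiquitin-protein ligase	23.1	1102
PKMR298	Punjabi	SEPT6	ChrX:118797529T>C	NM_145799.3	c.257A>G	p.(Tyr86Cys)	Missense	Filament formation	26.4	11.41
PKMR318	Punjabi	DUOX1	Chr15:45444197G>T	NM_175940.2	c.3140G>T	p.(Cys1047Phe)	Missense	Oxidase	22.9	16.59
PKMR320	Punjabi	SLC7A10	Chr19:33700282_83dupA	NM_019849.2	c.1372_1373dupA	p.(Thr458Asnfs*71)	Frameshift	Transporter	NA	16.49
PKMR325	Punjabi	TM2D3	Chr15:102182749G>A	NM_078474.2	c.677C>T	p.(Thr226Met)	Missense	Cell death or proliferation	31.0	8.344
PKMR326	Pathan	PRKAR2B	Chr7:106797706G>T	NM_002736.2	c.1060G>T	p.(Ala354Ser)	Missense	Kinase modulator	32.0	8.247
PKMR396	Punjabi	RGR	Chr10:86008779G>A	NM_002921.3	c.350G>A	p.(Arg117His)	Missense	Retinal G-protein coupled receptor	26.5	107.3
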