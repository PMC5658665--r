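family	gene	position	transcript	hgvs_c	hgvs_p	variation	cadd	exac_af_e6	omim	phenotype
PKMR08	GNE	Chr9:36217445C>T	NM_005476.5	c.2086G>A	p.(Val696Met)	Missense	32.0	1942	603824	D
PKMR29	POMT2	Chr14:77765840T>C	NM_013382.5	c.881A>G	p.(Tyr294Cys)	Missense	27.9	0	607439	O
PKMR36	APTX	Chr9:32984803delC	NM_001195248.1	c.638delG	p.(Arg213Leufs*15)	Frameshift	NA	8.238	606350	O
PKMR42	VPS13B	Chr8:100654333C>T	NM_017890.4	c.5590C>T	p.(Gln1864*)	Nonsense	NA	0	607817	O
PKMR51a	TSHR	Chr14:81610687C>T	NM_000369.2	c.2285C>T	p.(Thr762Met)	Missense	25.3	8.247	603372	D
PKMR61a	SCN1A	Chr2:166848284G>A	NM_001165963.1	c.5501C>T	p.(Ala1834Val)	Missense	32	8.241	182389	O
PKMR79	AP4M1	Chr7:99704430delG	NM_004722.3	c.1287delG	p.(Arg429Serfs*15)	Frameshift	NA	0	602296	O
PKMR82	KCNA2	Chr1:111147212G>A	NM_004974.3	c.193C>T	p.(Arg65*)	Nonsense	NA	8.239	176262	C
PKMR85	MED23	Chr6:131941859T>C	NM_004830.3	c.506A>G	p.(Tyr169Cys)	Missense	24.6	0	605042	C
PKMR86	FRAS1	Chr4:79202579C>T	NM_025074.6	c.1099C>T	p.(Arg367Cys)	Missense	24.4	43.14	607830	O
PKMR87	MAN2B1	Chr19:12763176C>G	NM_000528.3	c.1928+1C>G	p.(Phe642Phefs*2)	Aberrant splicing	NA	0	609458	O
PKMR97	MFSD2A	Chr1:40431565C>T	NM_001136493.2	c.632C>T	p.(Thr211Met)	Missense	33	8.239	614397	C
PKMR99	SYNE1	Chr6:152819877C>G	NM_182961.3	c.939G>C	p.(Lys313Asn)	Missense	21.9	28.33	608441	D
PKMR102	ASPM	Chr1:197087007C>T	NM_018136.4	c.3977G>A	p.(Trp1326*)	Nonsense	NA	8.255	605481	C
PKMR105	ZNF41	ChrX:47315776C>T	NM_007130.2	c.94G>A	p.(Val32Met)	Missense	30	0	314995	O
PKMR115	SRD5A3	Chr4:56212560G>A	NM_024592.4	c.57G>A	p.Trp19*	Nonsense	NA	357.1	611715	C
PKMR119	PGAP1	Chr2:197710616T>C	NM_024989.3	c.2276A>G	p.(Tyr759Cys)	Missense	23.6	16.57	611655	C
PKMR133	DOCK8	Chr9:286599G>A	NM_203447.3	c.295G>A	p.(Glu99Lys)	Missense	25.9	247.3	611432	C
PKMR151	TMEM67	Chr8:94768056G>A	NM_153704.5	c.274G>A	p.(Gly92Arg)	Missense	25.6	17.41	609884	O
PKMR152	WDR62	Chr19:36587982G>T	NM_001083961.1	c.2520+1G>T	p.(Leu840Leufs*95)	Aberrant splicing	NA	0	613583	C
PKMR184	SPG11	Chr15:44876109delA	NM_025137.3	c.5769delT	p.(Ser1923Argfs*28)	Frameshift	NA	41.18	610844	C
PKMR188	ASPA	Chr17:3402260G>A	NM_000049.2	c.820G>A	p.(Gly274Arg)	Missense	28.9	8.421	608034	C
PKMR193	ARL13B	Chr3:93755508G>A	NM_182896.2	c.599G>A	p.(Arg200His)	Missense	34	8.314	608922	C
PKMR212	ZFYVE26	Chr14:68268804_05delGA	NM_015346.3	c.1630_1631delTC	p.(Ser544Leufs*24)	Frameshift	NA	8.236	612012	C
PKMR216	AP4S1	Chr14:31539047A>G	NM_007077.4	c.139-2A>G	p.(Gln46Glnfs*85)	Aberrant splicing	NA	24.71	607243	C
PKMR224	MKKS	Chr20:10393388delT	NM_018848.3	c.775delA	p.(Thr259Leufs*21)	Frameshift	NA	74.18	604896	C
PKMR242	WDR73	Chr15:85186864A>G	NM_032856.3	c.974T>C	p.(Phe325Ser)	Missense	29.9	0	616144	O
PKMR264	FRY	Chr13:32747633G>A	NM_023037.2	c.2281G>A	p.(Val761Ile)	Missense	21.7	8.281	614818	O
PKMR281	GPT2	Chr16:46956326C>T	NM_133443.3	c.1210C>T	p.(Arg404*)	Nonsense	NA	33.31	138210	O
PKMR321	FLNA	ChrX:153583356G>A	NM_001110556.1	c.5054C>T	p.Thr1685Met	Missense	27.1	11.58	300017	C
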