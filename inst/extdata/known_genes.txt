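AP4M1
AP4S1
APTX
ARL13B
ASPA
ASPM
DOCK8
EXOSC8
FGFR1
FLNA
FRAS1
FRY
GNE
GPT2
KCNA2
MAN2B1
MED23
MFSD2A
MKKS
PGAP1
POMT2
SCN1A
SPG11
SRD5A3
SYNE1
TMEM67
TSHR
VPS13B
WDR62
WDR73
ZFYVE26
ZNF41
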