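name	motif
QKI	ACUAAC
RBFOX	UGCAUG
MBNL	YGCY
HNRNPC	UUUUU
PTBP1	CUCUCU
SRSF1	GGAGGA
NOVA	UCAUY
ELAVL1	AUUUA
TIA1	UUUUA
FUS	GGUG
SRSF2	SSNG
HNRNPA1	UAGGGW
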