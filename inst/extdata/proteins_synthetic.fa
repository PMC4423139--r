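>chicken_like synthetic (chicken-like)
CQCCVGDLKQPSCCDCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPC
QKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQQSVCCDPCQQS
VCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPC
QQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCC
DPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQSVCCDPCQQS
VCCDPCQQSVCCDPCQQSVKQCCVGCCKQCCVGCCKQCCVGCCKQCCVGCCKQCCVGCCK
QCCVGCCKQCCVGCCKQCCVGDLKQ
>falcon_like synthetic (falcon-like)
KQCCVGDCCQPSCCDPCQKPCCDPCQQSVCCDPCQKPCCDPCQQSVCCDPCQKPCCDPCQ
QSVCCDPCQKPCCDPCQQSVCCDPCQKPCCDPCQQSVCCDPCQKPCCDPCQQSVCCDPCQ
KPCCDPCQQSVCCDPCQKPCCDPCQQSVCCDPCQKPCCDPCQQSVCCDPCQKPCCDPCQQ
SVCCDPCQKPCCDPCQQSVCCDPCQKPCCDPCQQSVCCDPCQKPCCDPCQQSVCCDPCQK
PCCDPCQQSVKQCCVGDCCQPSCCDLKCCSVGCCKQPCCGDLCCPSVCCLKQCCVGDCCQ
PSVGDLKQPS
>ostrich_like synthetic (ostrich-like)
KQCCVGDLKQPSVGDCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPC
QKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPC
CDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPCCDPCQKPKQCCV
GDLKQPSCCDLKQPSVGCCKQPSVGDLCCPSVGDLKQCCVGDLKQPSCCDLKQPSVGDLK
QPSVG
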