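>lizard_EDCRP_like synthetic (lizard-like)
KQCCVGDLKQPSCCCCDPCQKTVCCDPCQTCCDPCQKTVCCDPCQTCCDPCQKTVCCDPC
QTCCDPCQKTVCCDPCQTCCDPCQKTVCCDPCQTCCDPCQKTVCCDPCQTCCDPCQKTVC
CDPCQTCCDPCQKTVCCDPCQTKQCCVGDCCQPSCCDLKCCSVGCCKQPCCGDLCCPSVC
CLKQCCVGDLKQPSVGD
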