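>KRTAP_like_1 synthetic (KRTAP-like)
MSCCCDPCQSSCCDPCQSSCCDPCQSSCCDPCQSSCCDPCQSSCCDPCQSSCCDPCQSSC
CDPCQSSCCDPCQSSCCDPCQSSCCQPSCQSCCQPSCQSCCQPSCQSCCQPSCQSCCQPS
CQS
>KRTAP_like_2 synthetic (KRTAP-like)
MACCCQPCCQSVCCQPCCQSVCCQPCCQSVCCQPCCQSVCCQPCCQSVCCQPCCQSVCCQ
PCCQSVCCQPCCQSVCCDPSCQTCCDPSCQTCCDPSCQTCCDPSCQT
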