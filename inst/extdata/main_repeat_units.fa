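>unit_KP KP
CCDPCQKP
>unit_KTSV K(T/S)V
CCDPCQKTV
>unit_TS (T/S)
CCDPCQT
>unit_QSV QS(V)
CCDPCQQSV
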