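size	class	count
3	high	690
3	medium	1002
3	low	4633
4	high	684
4	medium	1239
4	low	2399
5	high	583
5	medium	979
5	low	1141
6	high	323
6	medium	528
6	low	434
7	high	121
7	medium	233
7	low	183
8	high	35
8	medium	57
8	low	52
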