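1	4999999	6500000	SW01
1	29999999	31200000	SW02
1	74999999	76800000	SW03
2	9999999	11500000	SW04
2	39999999	41000000	SW05
2	61999999	63100000	SW06
3	19999999	21300000	SW07
3	44999999	45900000	SW08
3	63759999	64990000	SW09
4	4999999	6200000	SW10
4	34999999	36400000	SW11
5	14999999	16100000	SW12
5	44999999	46300000	SW13
6	9999999	10900000	SW14
6	29999999	30800000	SW15
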