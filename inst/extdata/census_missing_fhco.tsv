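size	category	count
2	period	3759
2	spike_frequency	3679
2	duty_cycle	26449
2	period_spike_frequency_duty_cycle	51
2	period_spike_frequency	496
2	period_duty_cycle	3691
2	spike_frequency_duty_cycle	4324
3	period	2188
3	spike_frequency	1597
3	duty_cycle	16102
3	period_spike_frequency_duty_cycle	31
3	period_spike_frequency	288
3	period_duty_cycle	1923
3	spike_frequency_duty_cycle	1716
4	period	1286
4	spike_frequency	598
4	duty_cycle	9538
4	period_spike_frequency_duty_cycle	22
4	period_spike_frequency	154
4	period_duty_cycle	1087
4	spike_frequency_duty_cycle	633
5	period	656
5	spike_frequency	195
5	duty_cycle	4643
5	period_spike_frequency_duty_cycle	22
5	period_spike_frequency	96
5	period_duty_cycle	559
5	spike_frequency_duty_cycle	216
6	period	162
6	spike_frequency	57
6	duty_cycle	1628
6	period_spike_frequency_duty_cycle	0
6	period_spike_frequency	3
6	period_duty_cycle	146
6	spike_frequency_duty_cycle	37
7	period	31
7	spike_frequency	9
7	duty_cycle	393
7	period_spike_frequency_duty_cycle	0
7	period_spike_frequency	0
7	period_duty_cycle	24
7	spike_frequency_duty_cycle	2
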