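test,measured_radius_cm
1,9.2
2,9.18
3,9.8
4,9.73
5,9.55
6,9.66
7,9.33
8,10.01
9,10.19
10,10.02
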