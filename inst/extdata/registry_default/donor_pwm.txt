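# donor 9-mer probability PWM, positions -3..+6 around the 5' splice site
# (3 exonic + 6 intronic bases); rows A, C, G, T; synthetic consensus-derived
>donor
0.33 0.60 0.08 0.002 0.002 0.60 0.70 0.05 0.16
0.36 0.13 0.04 0.002 0.002 0.03 0.08 0.05 0.17
0.18 0.14 0.81 0.994 0.002 0.34 0.10 0.84 0.19
0.13 0.13 0.07 0.002 0.994 0.03 0.12 0.06 0.48
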