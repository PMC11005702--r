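# acceptor 23-mer probability PWM, positions -20..+3 around the 3' splice
# site (20 intronic + 3 exonic bases); rows A, C, G, T; synthetic
# consensus-derived
>acceptor
0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.23 0.05 0.994 0.002 0.25 0.25 0.25
0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.30 0.64 0.002 0.002 0.12 0.25 0.25
0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.10 0.22 0.03 0.002 0.994 0.50 0.25 0.25
0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.50 0.25 0.28 0.002 0.002 0.13 0.25 0.25
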