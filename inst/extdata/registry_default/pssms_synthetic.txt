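# synthetic log2-odds PSSMs (rows A, C, G, T) shipped as defaults;
# replace with a curated registry for real analyses
>QKIlike
 2.0 -2.0 -2.0  1.5  1.5 -2.0
-2.0  1.8 -2.0 -2.0 -2.0  1.8
-2.0 -2.0 -2.0 -2.0 -2.0 -2.0
-2.0 -2.0  1.8 -2.0 -2.0 -2.0
>GArich
 1.2 -1.5  1.2 -1.5  1.2 -1.5
-1.5 -1.5 -1.5 -1.5 -1.5 -1.5
 0.8  1.5  0.8  1.5  0.8  1.5
-1.5 -1.5 -1.5 -1.5 -1.5 -1.5
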