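snp_no,position,alleles,reported_freq
1,6,A/C,0.01
2,24,G/C,0.01
3,39,A/G/C,0.20/0.19
4,42,A/C,0.27
5,45,T/C,0.21
6,48,G/C,0.88
7,51,A/G,0.59
8,54,A/G,0.51
9,60,G/C,0.85
10,69,G/C,0.54
11,72,G/C,0.08
12,84,G/C,0.52
13,99,G/C,0.42
14,114,A/C,0.20
15,138,G/C,0.76
16,156,G/C,0.21
17,189,G/C,0.85
18,206,G/C,0.02
19,222,A/G,0.94
20,228,T/G,0.02
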