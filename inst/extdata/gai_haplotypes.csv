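haplotype_no,haplotype,count
1,CCAACGGAGGGGGCGCGCAG,1
2,CCACTGAAGCCGGCGCGCAG,66
3,CCACTGAAGCCGGCGGGCAG,1
4,CCACCGAGCGCCCCGCGCAG,1
5,CCACCGGAGGGGGCGCGCAG,3
6,CCGATGGGGCCGCCGCGCAG,1
7,CCGACGGAGGGGCCGCGCAG,1
8,CCGACGGGGCCGGCGCGCAG,3
9,CCGACGGGGCCGGCGCCCAG,57
10,CCGACGGGGCCGCCGCGCAG,17
11,CCGACGGGGCCGCAGCGCAG,3
12,CCGACGGGGCCCCCGCGCAG,1
13,CCGACGGGGGCCGCGCCCAG,1
14,CCGACGGGGGCCGCGGGCAG,2
15,CCGACCAGGCCGGCGCGCAG,14
16,CCGACCGGGCCCCCCCGCAG,1
17,CCGCTGAAGCCCGCGCGCAG,1
18,CCGCTGAACGCCGCGCGCAG,3
19,CCGCTGGAGCCCGCGCGCAG,1
20,CCGCTGGGGCCGGCGCGCAG,1
21,CCGCCGAAGGCCCCGCGCAG,3
22,CCGCCGAAGGCCCCCCGGGT,8
23,CCGCCGAAGGCCCACCGCAG,1
24,CCGCCGAAGGCCCACGGCAG,56
25,CCGCCGAAGGCCCACGGCGG,15
26,CCGCCGAGCGCGCCGCGCAG,1
27,CCGCCGAGCGCCCCGCGCAG,50
28,CCGCCGGAGGCCCCGCGCAG,2
29,CCGCCGGAGGGGGCGCGCAG,1
30,CCGCCGGAGGGGCCGCGCAG,18
31,CCGCCGGAGGGGCCCCGCAG,5
32,CCGCCGGAGGGCCCGCGCAG,1
33,CCGCCGGACGCCCCCGGCAG,3
34,CCGCCGGGGGCCCCGCGCAG,3
35,CCGCCGGGGGCCCCGGGCAG,1
36,CCGCCCGGGCCCCCCCGCAG,3
37,CCGCCCGGGGCCCCGCGCAG,26
38,CGGCCCGAGGCGCCCGGCAG,1
39,ACACTGAAGCCGGCGCGCAG,3
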