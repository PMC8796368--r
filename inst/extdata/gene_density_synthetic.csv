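"chrom","genes_per_mb"
1,9.5
2,6.2
3,5.4
4,4.4
5,5
6,5.9
7,6.3
8,5
9,6.3
10,5.7
11,9.7
12,7.8
13,3.4
14,6.8
15,7.3
16,9.7
17,14.5
18,4.2
19,24.4
20,8.7
21,5.6
22,9.8
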