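2 14 15
14 15 16
15 16 17
16 17 18
17 18 19
18 19 20
19 20 21
20 21 22
21 22 23
22 23 8
3 24 25
24 25 26
25 26 27
26 27 28
27 28 29
28 29 30
29 30 31
30 31 32
31 32 33
32 33 9
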