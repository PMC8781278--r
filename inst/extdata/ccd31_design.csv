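run_id,S,N,T,I
1,225,300,20,5e5
2,150,100,30,0
3,150,500,10,0
4,150,100,10,0
5,225,300,20,5e5
6,225,300,30,5e5
7,300,500,10,1e6
8,300,100,10,1e6
9,150,100,30,1e6
10,300,500,30,0
11,300,300,20,5e5
12,225,300,20,0
13,225,300,10,5e5
14,225,300,20,5e5
15,225,300,20,1e6
16,150,500,30,0
17,150,500,30,1e6
18,150,500,10,1e6
19,225,300,20,5e5
20,225,300,20,5e5
21,300,500,30,1e6
22,150,300,20,5e5
23,300,100,10,0
24,300,100,30,1e6
25,225,100,20,5e5
26,150,100,10,1e6
27,300,500,10,0
28,225,300,20,5e5
29,300,100,30,0
30,225,300,20,5e5
31,225,500,20,5e5
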