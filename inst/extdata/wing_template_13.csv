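landmark,x,y
1,0.0,0.0
2,1.2,0.9
3,2.5,1.2
4,3.9,1.4
5,2.9,0.2
6,4.6,0.5
7,5.8,1.1
8,6.4,0.3
9,4.4,-0.7
10,5.9,-0.9
11,7.3,-0.4
12,8.2,0.4
13,9.5,0.8
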