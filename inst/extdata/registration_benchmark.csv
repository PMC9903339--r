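"sample","features_before","features_after","homography_error_px","control_point_error_px"
1,41,65,0.4,3.3
2,51,55,0.5,2.8
3,32,61,1,3.5
4,26,61,0.3,2.1
5,20,34,0.3,2.7
6,33,54,0.5,1.9
7,42,68,0.3,2
8,10,28,0.8,3.1
9,71,78,0.9,3.3
10,26,35,0.5,2.2
11,48,68,0.3,1.8
12,60,81,0.6,3.3
13,42,63,0.7,3.7
14,47,79,1,3.3
15,24,60,0.7,4.2
16,35,71,0.5,2.7
17,41,52,0.4,4
18,28,65,0.3,2.6
19,34,67,0.6,2.4
20,38,65,0.6,1.9
21,28,42,0.4,4.5
22,21,40,0.5,2.2
23,46,38,0.3,3.5
24,29,35,0.3,2.8
25,66,81,0.4,3.1
26,47,66,0.6,2.6
27,34,49,0.5,3.4
28,75,89,0.5,2.5
29,31,42,0.3,2.2
30,51,49,0.7,2.3
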