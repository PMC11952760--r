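value,printed_digit
0.01,1
0.01,1
0.01,1
0.01,1
0.01,1
0.01,1
0.01,1
0.01,1
0.01,1
0.01,1
0.01,1
0.01,1
0.1,1
0.11,1
0.11,1
0.11,1
0.12,1
0.14,1
0.14,1
0.14,1
0.15,1
0.16,1
0.16,1
0.16,1
0.17,1
0.17,1
0.18,1
0.19,1
1.06,1
1.08,1
1.1,1
1.2,1
1.2,1
1.52,1
1.68,1
1.71,1
1.98,1
10.52,1
11.03,1
12,1
14.11,1
14.72,1
15.8,1
16.94,1
18.22,1
19.5,1
114.5,1
0.02,2
0.02,2
0.02,2
0.02,2
0.02,2
0.02,2
0.02,2
0.02,2
0.02,2
0.02,2
0.2,2
0.2,2
0.21,2
0.29,2
2,2
2,2
2.07,2
2.23,2
2.25,2
2.41,2
2.49,2
2.8,2
2.8,2
2.85,2
21.01,2
21.3,2
21.35,2
0.03,3
0.03,3
0.03,3
0.03,3
0.03,3
0.03,3
0.03,3
0.32,3
0.34,3
3.2,3
3.2,3
3.6,3
3.68,3
3.7,3
32.99,3
33.6,3
34.3,3
38.03,3
0.04,4
0.04,4
0.04,4
0.04,4
0.04,4
0.04,4
0.4,4
0.46,4
0.48,4
4,4
4.01,4
4.8,4
44.9,4
48.17,4
0.05,5
0.05,5
0.05,5
0.56,5
0.56,5
5.1,5
5.2,5
5.51,5
5.67,5
53.85,5
0.06,6
0.06,6
0.6,6
0.63,6
0.64,6
0.64,6
0.69,6
6.3,6
6.7,6
62.25,6
67.5,6
0.07,7
0.73,7
0.76,7
70.18,7
0.08,8
0.08,8
0.87,8
80.82,8
0.09,9
0.09,9
0.9,9
0.99,9
9,9
9.31,9
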