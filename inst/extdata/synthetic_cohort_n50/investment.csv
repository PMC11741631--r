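period,fte_costs,non_fte_costs
1,428116.12,96065.56
2,399073.84,145508.85
3,454193.36,90717.06
4,482167.27,66609.74
5,404907.52,78589.92
6,420686.68,72269.12
7,494386.74,91530.68
8,534119.68,142287.62
9,452778.15,71433.66
10,423261.5,75496.37
11,486085.15,94588.42
12,430608.57,86312.06
13,411607.52,76326.25
14,521164.05,93840.87
15,370458.35,103046.34
16,460899.13,144295.26
17,455992.89,98533.81
18,484015.57,89143.97
19,430577.86,91237.1
20,528350.88,66865.33
21,562761.1,75405.65
22,448996.76,132110.81
23,508474.28,78650.75
24,437485.27,100949.72
25,434238.34,89997.33
26,420937.41,79999.9
27,419665.6,85248.7
28,493485.64,118678.13
29,468555.02,86390.01
30,460073.15,106470.61
31,483619.82,108777.04
32,384950.05,72251.15
33,407052.84,87718.06
34,426441.12,107038.22
35,427472.95,75745.64
36,482365.75,71344.28
37,515486.55,102279.47
38,476455.56,79564.63
39,459243.95,131435.78
40,463099.25,47921.15
41,419697.67,95515.78
42,497228.67,119937.06
43,512003.77,116863.54
44,420025.57,105874.52
45,469705.94,117704.06
46,437817.39,78502.67
47,391467.93,75739.39
48,429187.01,97093.94
49,509572.98,73399.04
50,350831.59,104826.06
51,461050.93,74539.26
52,555647.54,100866.93
53,418438.68,115934.68
54,425907.04,77918.13
55,383215.2,102506.6
56,404573.24,81751.29
57,503960.7,76035.49
58,444255.19,86528.4
59,435332.67,112652.56
60,447742.66,86077.87
61,415869.96,116103.15
62,390522.28,125905.61
63,436475.39,55694.47
64,460001.7,88261.34
65,470285.61,92124.9
66,534017.24,79306.94
67,396931.75,128621.59
68,440289.23,118537.48
69,419071.35,70921.44
70,502689.27,87481.86
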