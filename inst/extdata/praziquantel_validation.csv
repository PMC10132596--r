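sample_id,a240,a250,a260,a270,substance,truth,sorted_category
1,0.776,0.532,0.439,0.365,Praziquantel & Ivermectin (proxy LQ),lqc,LQ/C
2,0.339,0.252,0.164,0.142,Sodium Bicarbonate (C),lqc,LQ/C
3,0.907,0.584,0.56,0.478,Praziquantel (A),authentic,A
4,0.393,0.278,0.147,0.123,Sodium Sulfate (C),lqc,LQ/C
5,0.43,0.281,0.136,0.114,Splenda (C),lqc,LQ/C
6,0.322,0.246,0.163,0.135,Sodium Chloride (C),lqc,LQ/C
7,0.862,0.565,0.522,0.448,Praziquantel (A),authentic,A
8,0.678,0.317,0.349,0.364,Sweet n' Low (C),lqc,LQ/C
9,0.43,0.281,0.136,0.114,Splenda (C),lqc,LQ/C
10,2,2,2,2,4-biphenyl methanol (C),lqc,LQ/C
11,0.678,0.317,0.349,0.364,Sweet n' Low (C),lqc,LQ/C
12,1.253,1.153,1.059,0.972,Pepper (C),lqc,LQ/C
13,0.714,0.45,0.474,0.412,Praziquantel (A),authentic,A
14,0.393,0.278,0.147,0.123,Sodium Sulfate (C),lqc,LQ/C
15,2,1.688,2,2,methyl-triphenylphosphonium bromide,lqc,LQ/C
16,0.322,0.246,0.163,0.135,Sodium Chloride (C),lqc,LQ/C
17,0.357,0.194,0.203,0.205,Sweet n' Low (C),lqc,LQ/C
18,0.887,0.566,0.516,0.439,Praziquantel (A),authentic,A
19,0.434,0.287,0.128,0.104,Sugar (C),lqc,LQ/C
20,0.471,0.91,1.779,1.485,Phenylboronic Acid (C),lqc,LQ/C
21,0.423,0.294,0.152,0.129,Sugar (C),lqc,LQ/C
22,1.12,0.838,0.272,0.135,Ivermectin (C),lqc,LQ/C
23,0.888,0.667,0.238,0.132,Ivermectin (C),lqc,LQ/C
24,1.51,0.324,0.153,0.136,Sodium Nitrate (C),lqc,LQ/C
25,0.15,0.099,0.083,0.077,Myristic Acid (C),lqc,LQ/C
26,0.15,0.099,0.083,0.077,Myristic Acid (C),lqc,LQ/C
27,0.61,0.611,0.904,0.889,4-chlorobenzyl Alcohol (C),lqc,LQ/C
28,0.447,0.328,0.183,0.16,Magnesium Sulfate (C),lqc,LQ/C
29,0.423,0.294,0.152,0.129,Sugar (C),lqc,LQ/C
30,0.472,0.321,0.199,0.198,Coffee (C),lqc,LQ/C
31,0.414,0.288,0.143,0.12,Splenda (C),lqc,LQ/C
32,0.357,0.194,0.203,0.205,Sweet n' Low (C),lqc,LQ/C
33,1.245,0.921,0.273,0.117,Ivermectin (C),lqc,LQ/C
34,1.253,1.153,1.059,0.972,Pepper (C),lqc,LQ/C
35,2,1.688,2,2,methyl-triphenylphosphonium bromide,lqc,LQ/C
36,1.51,0.324,0.153,0.136,Sodium Nitrate (C),lqc,LQ/C
37,0.471,0.91,1.779,1.485,Phenylboronic Acid (C),lqc,LQ/C
38,0.414,0.288,0.143,0.12,Splenda (C),lqc,LQ/C
39,1.68,1.839,1.282,0.747,Ivermectin (C),lqc,LQ/C
40,2,2,2,2,4-biphenyl methanol (C),lqc,LQ/C
41,0.393,0.331,0.227,0.173,Sodium Sulfite (C),lqc,LQ/C
42,0.393,0.331,0.227,0.173,Sodium Sulfite (C),lqc,LQ/C
43,0.434,0.287,0.128,0.104,Sugar (C),lqc,LQ/C
44,0.472,0.321,0.199,0.198,Coffee (C),lqc,LQ/C
45,0.558,0.379,0.373,0.318,Azithromycin & Praziquantel (Proxy LQ),lqc,LQ/C
46,0.776,0.532,0.439,0.365,Praziquantel & Ivermectin (proxy LQ),lqc,LQ/C
47,0.61,0.611,0.904,0.889,4-chlorobenzyl Alcohol (C),lqc,LQ/C
48,0.339,0.252,0.164,0.142,Sodium Bicarbonate (C),lqc,LQ/C
49,1.101,0.829,0.259,0.124,Ivermectin (C),lqc,LQ/C
50,0.447,0.328,0.183,0.16,Magnesium Sulfate (C),lqc,LQ/C
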