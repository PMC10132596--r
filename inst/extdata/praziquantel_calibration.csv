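sample_id,a240,a250,a260,a270,substance,truth
1,0.471,0.91,1.779,1.485,Phenylboronic Acid,lqc
2,0.558,0.379,0.373,0.318,Azithromycin & Praziquantel,lqc
3,1.51,0.324,0.153,0.136,Sodium Nitrate,lqc
4,0.714,0.45,0.474,0.412,Praziquantel,authentic
5,0.15,0.099,0.083,0.077,Myristic Acid,lqc
6,0.61,0.611,0.904,0.889,4-chlorobenzyl Alcohol,lqc
7,2,2,2,2,4-biphenyl methanol,lqc
8,0.393,0.331,0.227,0.173,Sodium Sulfite,lqc
9,0.322,0.246,0.163,0.135,Sodium Chloride,lqc
10,0.339,0.252,0.164,0.142,Sodium Bicarbonate,lqc
11,0.776,0.532,0.439,0.365,Praziquantel & Ivermectin,lqc
12,0.447,0.328,0.183,0.16,Magnesium Sulfate,lqc
13,2,1.688,2,2,methyl-triphenylphosphonium bromide,lqc
14,0.862,0.565,0.522,0.448,Praziquantel,authentic
15,0.393,0.278,0.147,0.123,Sodium Sulfate,lqc
16,0.357,0.194,0.203,0.205,Sweet n' Low,lqc
17,0.423,0.294,0.152,0.129,Sugar,lqc
18,0.414,0.288,0.143,0.12,Splenda,lqc
19,0.887,0.566,0.516,0.439,Praziquantel,authentic
20,0.472,0.321,0.199,0.198,Coffee,lqc
21,0.434,0.287,0.128,0.104,Sugar,lqc
22,0.678,0.317,0.349,0.364,Sweet n' Low,lqc
23,0.43,0.281,0.136,0.114,Splenda,lqc
24,1.253,1.153,1.059,0.972,Pepper,lqc
25,0.907,0.584,0.56,0.478,Praziquantel,authentic
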