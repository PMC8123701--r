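item,dimension,reverse,ref_item_mean,ref_item_sd
1,extraversion,FALSE,3.29,0.75
2,extraversion,FALSE,3.27,0.95
3,extraversion,FALSE,3.29,0.75
4,extraversion,FALSE,3.56,0.74
5,extraversion,FALSE,3.61,0.77
6,extraversion,FALSE,3.44,0.78
7,agreeableness,FALSE,3.34,0.79
8,agreeableness,FALSE,3.54,0.74
9,agreeableness,FALSE,3.66,0.76
10,agreeableness,TRUE,3.39,1.00
11,agreeableness,FALSE,3.68,0.76
12,agreeableness,FALSE,3.71,0.64
13,agreeableness,FALSE,3.66,0.69
14,agreeableness,FALSE,3.61,0.80
15,conscientiousness,FALSE,3.76,0.62
16,conscientiousness,FALSE,3.73,0.59
17,conscientiousness,FALSE,3.61,0.67
18,conscientiousness,FALSE,3.66,0.57
19,conscientiousness,FALSE,3.46,0.71
20,conscientiousness,TRUE,3.15,1.01
21,neuroticism,FALSE,2.95,0.97
22,neuroticism,TRUE,2.39,0.70
23,neuroticism,FALSE,3.07,0.82
24,neuroticism,TRUE,2.56,0.78
25,neuroticism,FALSE,2.78,0.91
26,neuroticism,FALSE,3.27,0.87
27,neuroticism,TRUE,2.39,0.74
28,openness,FALSE,3.39,0.80
29,openness,FALSE,3.41,0.81
30,openness,FALSE,3.51,0.75
31,openness,TRUE,2.93,0.79
32,openness,FALSE,3.49,0.81
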