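compound_id,pec50_exp,pec50_calc_ff,res_ff,pec50_calc_gf,res_gf
1,8.921,8.996,-0.075,8.404,0.518
2,8.585,8.836,-0.251,9.127,-0.542
3,7.398,8.416,-1.018,7.211,0.187
4,7.509,7.745,-0.236,7.716,-0.207
5,5.648,6.033,-0.385,5.894,-0.246
6,6.284,6.418,-0.134,6.683,-0.399
7,6.331,5.984,0.347,6.177,0.154
8,6.133,6.173,-0.040,6.098,0.035
9,8.699,8.736,-0.037,8.733,-0.034
10,7.141,8.076,-0.935,7.222,-0.081
11,7.703,7.675,0.028,7.967,-0.264
12,6.067,6.801,-0.734,6.559,-0.492
13,8.244,7.459,0.785,8.088,0.156
14,8.000,7.932,0.068,8.196,-0.196
15,8.009,7.568,0.441,7.775,0.234
16,8.824,8.294,0.530,8.722,0.102
17,8.469,7.331,1.138,7.541,0.928
18,9.301,8.681,0.620,9.184,0.117
19,6.301,6.646,-0.345,5.982,0.319
20,5.867,6.333,-0.466,6.292,-0.425
21,7.658,7.808,-0.150,7.641,0.017
22,7.237,7.235,0.002,7.383,-0.146
23,7.469,8.233,-0.764,7.944,-0.475
24,7.745,7.490,0.255,7.766,-0.021
25,7.738,7.225,0.513,7.848,-0.110
26,7.409,7.349,0.060,7.366,0.043
27,7.301,7.367,-0.066,7.527,-0.226
28,7.959,8.241,-0.282,7.843,0.116
29,6.076,6.727,-0.651,6.162,-0.086
30,8.319,7.986,0.333,7.491,0.829
31,8.284,8.662,-0.378,8.659,-0.375
32,7.246,6.825,0.421,6.993,0.253
33,6.842,7.797,-0.955,8.065,-1.223
34,6.315,6.676,-0.361,6.240,0.076
35,7.268,6.893,0.375,7.441,-0.173
36,6.942,6.924,0.018,7.180,-0.238
37,8.310,8.321,-0.011,8.586,-0.276
38,9.523,9.551,-0.028,9.631,-0.108
39,8.060,7.735,0.325,7.305,0.755
40,8.076,8.292,-0.216,7.911,0.165
41,7.102,8.080,-0.978,8.083,-0.981
42,6.223,5.805,0.418,5.591,0.632
43,5.712,6.893,-1.181,6.000,-0.288
44,7.983,7.459,0.524,7.512,0.471
45,5.712,5.226,0.486,6.499,-0.787
46,8.824,9.078,-0.254,9.024,-0.200
47,9.155,8.822,0.333,8.597,0.558
48,7.208,7.169,0.039,6.673,0.535
49,7.009,6.466,0.543,7.435,-0.426
50,6.120,6.400,-0.280,6.303,-0.183
51,9.222,9.270,-0.048,9.368,-0.146
52,7.866,7.670,0.196,7.525,0.341
53,10.000,8.778,1.222,8.970,1.030
54,8.046,8.168,-0.122,7.983,0.063
55,6.099,6.030,0.069,5.722,0.377
56,8.056,7.701,0.355,8.100,-0.044
57,8.886,8.488,0.398,9.006,-0.120
58,9.523,8.838,0.685,8.928,0.595
59,9.398,9.487,-0.089,9.815,-0.417
60,5.963,6.700,-0.737,6.536,-0.573
61,7.678,6.177,1.501,6.403,1.275
62,7.377,7.497,-0.120,8.061,-0.684
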