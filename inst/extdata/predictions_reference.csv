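"compound","experimental","comfa_predicted","comsia_predicted","test_set","comfa_outlier","comsia_outlier"
1,6.538,6.263,6.435,TRUE,FALSE,FALSE
2,6.745,6.76,6.743,FALSE,FALSE,FALSE
3,6.553,6.532,6.552,FALSE,FALSE,FALSE
4,6.602,6.61,6.596,FALSE,FALSE,FALSE
5,6.482,6.494,6.496,FALSE,FALSE,FALSE
6,6.553,6.811,6.444,TRUE,FALSE,FALSE
7,5.602,5.559,5.635,FALSE,FALSE,FALSE
8,5.018,4.969,4.646,TRUE,FALSE,FALSE
9,6.187,6.205,6.197,FALSE,FALSE,FALSE
10,6.745,6.761,6.651,TRUE,FALSE,FALSE
11,6.854,7.136,6.83,TRUE,FALSE,FALSE
12,6.886,6.893,6.965,FALSE,FALSE,FALSE
13,6.569,6.667,6.721,FALSE,FALSE,FALSE
14,6.721,6.707,6.826,TRUE,FALSE,FALSE
15,6.585,6.601,6.569,FALSE,FALSE,FALSE
16,7.208,7.144,6.953,FALSE,FALSE,FALSE
17,6.553,6.53,6.632,FALSE,FALSE,FALSE
18,6.301,5.853,6.601,TRUE,TRUE,FALSE
19,5.699,5.636,5.613,FALSE,FALSE,FALSE
20,4.921,5.049,4.908,FALSE,FALSE,FALSE
21,3.886,3.794,3.894,FALSE,FALSE,FALSE
22,5.032,5.157,4.98,FALSE,FALSE,FALSE
23,5.721,6.157,5.908,TRUE,TRUE,FALSE
24,6.357,6.362,6.549,FALSE,FALSE,FALSE
25,5.854,5.818,5.979,FALSE,FALSE,FALSE
26,6.328,6.331,6.345,FALSE,FALSE,FALSE
27,6.292,6.269,6.303,FALSE,FALSE,FALSE
28,6.398,6.288,6.404,FALSE,FALSE,FALSE
29,6.569,6.604,6.605,FALSE,FALSE,FALSE
30,6.553,6.601,6.534,FALSE,FALSE,FALSE
31,6.469,6.539,6.403,FALSE,FALSE,FALSE
32,7,6.984,6.964,FALSE,FALSE,FALSE
33,7,6.921,6.904,FALSE,FALSE,FALSE
34,6.569,6.244,6.539,TRUE,FALSE,FALSE
35,6.796,6.835,6.71,FALSE,FALSE,FALSE
36,6.699,6.696,6.572,FALSE,FALSE,FALSE
37,6.638,6.503,6.448,TRUE,FALSE,FALSE
38,6.638,6.57,6.601,FALSE,FALSE,FALSE
39,6.77,6.781,6.902,FALSE,FALSE,FALSE
40,6.495,6.678,6.91,TRUE,FALSE,TRUE
41,6.187,6.39,6.718,TRUE,FALSE,TRUE
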