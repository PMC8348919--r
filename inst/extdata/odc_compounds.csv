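compound_id,r1,r2,r3,ic50_um,pic50,pred_comfa,pred_comsia,split,pharmacophore_set,smiles
01,methyl,H,O,0.0920,7.0362,6.984,7.075,test,FALSE,
02,iso-propyl,H,O,0.0737,7.1325,7.167,7.132,train,FALSE,
03,iso-butyl,H,O,0.0644,7.1911,7.204,7.192,train,FALSE,
04,iso-pentyl,H,O,0.0541,7.2668,7.250,7.255,train,FALSE,
05,allyl,H,O,0.0437,7.3595,7.407,7.329,test,TRUE,
06,iso-butenyl,H,O,0.0569,7.2449,7.246,7.253,train,FALSE,
07,iso-pentenyl,H,O,0.0692,7.1599,7.163,7.146,train,FALSE,
08,propinyl,H,O,0.0500,7.3010,7.263,7.302,train,TRUE,
09,methylenecyclopropane,H,O,0.0461,7.3363,7.324,7.328,train,TRUE,
10,cyclopentyl,H,O,0.0585,7.2328,7.275,7.235,train,FALSE,
11,methylenecyclohexane,H,O,0.0683,7.1656,7.143,7.144,train,FALSE,
12,benzyl,H,O,0.0945,7.0246,7.102,7.018,train,FALSE,
13,p-methylbenzyl,H,O,0.0894,7.0487,7.074,7.106,train,FALSE,
14,p-tert-butylbenzyl,H,O,0.1490,6.8268,6.804,6.801,test,FALSE,
15,p-methoxylbenzyl,H,O,0.0507,7.2950,7.330,7.301,train,FALSE,
16,p-fluorobenzyl,H,O,0.0531,7.2749,7.226,7.211,train,FALSE,
17,p-chlorobenzyl,H,O,0.0691,7.1605,7.195,7.201,train,FALSE,
18,p-bromobenzyl,H,O,0.0552,7.2581,7.194,7.233,train,FALSE,
19,m-methoxylbenzyl,H,O,0.0516,7.2874,7.273,7.301,train,FALSE,
20,m-fluorobenzyl,H,O,0.0477,7.3215,7.298,7.319,train,FALSE,
21,m-chlorobenzyl,H,O,0.0288,7.5406,7.593,7.535,test,TRUE,
22,m-bromobenzyl,H,O,0.0450,7.3468,7.329,7.342,train,FALSE,
23,o-chlorobenzyl,H,O,0.0917,7.0376,7.062,7.004,train,FALSE,
24,"2,5-dichlorobenzyl",H,O,0.0639,7.1945,7.120,7.215,train,FALSE,
25,"2,4-dichlorobenzyl",H,O,0.0838,7.0768,7.129,7.116,train,FALSE,
26,hydrogen,H,O,0.6290,6.2013,6.205,6.201,train,FALSE,
27,iso-propyl,H,O,0.0916,7.0381,7.013,7.042,train,FALSE,
28,iso-butyl,H,O,0.0609,7.2154,7.238,7.270,test,FALSE,
29,iso-pentyl,H,O,0.0250,7.6021,7.561,7.705,test,TRUE,
30,allyl,H,O,0.0811,7.0910,7.107,7.026,test,FALSE,
31,iso-butenyl,H,O,0.0336,7.4737,7.505,7.507,train,TRUE,
32,iso-pentenyl,H,O,0.0388,7.4112,7.389,7.429,train,FALSE,
33,benzyl,H,O,0.0387,7.4123,7.297,7.405,test,FALSE,
34,p-fluorobenzyl,H,O,0.0382,7.4179,7.424,7.398,train,FALSE,
35,p-chlorobenzyl,H,O,0.0499,7.3019,7.405,7.410,train,FALSE,
36,p-bromobenzyl,H,O,0.0298,7.5258,7.426,7.462,train,TRUE,
37,p-tert-butylbenzyl,H,O,0.1970,6.7055,6.874,6.787,test,TRUE,
38,p-methylbenzyl,H,O,0.0354,7.4510,7.391,7.380,train,FALSE,
39,iso-pentyl,CH3,O,0.5400,6.2676,6.256,6.248,train,FALSE,
40,iso-butenyl,CH3,O,0.5677,6.2459,6.253,6.263,train,FALSE,
41,p-bromobenzyl,CH3,O,0.1854,6.7319,6.822,6.512,test,FALSE,
42,p-methylbenzyl,CH3,O,0.1590,6.7986,6.807,6.469,test,FALSE,
43,iso-pentyl,H,NH,0.0240,7.6198,7.664,7.642,train,TRUE,
44,iso-butenyl,H,NH,0.0181,7.7423,7.684,7.708,train,TRUE,
45,p-bromobenzyl,H,NH,0.0271,7.5670,7.580,7.558,train,TRUE,
46,p-methylbenzyl,H,NH,0.0339,7.4698,7.528,7.487,train,FALSE,
Febuxostat,,,,0.0236,7.6271,,,reference,TRUE,CC(C)COc1ccc(cc1C#N)c1nc(c(s1)C(=O)O)C
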