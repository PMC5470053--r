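# auc=0.918 direction=lt
cutpoint	se	sp
3.095	0.92	0.44
2.986	0.92	0.48
2.727	0.92	0.52
2.527	0.92	0.56
2.478	0.92	0.60
2.416	0.92	0.64
2.331	0.92	0.68
2.284	0.92	0.72
2.262	0.92	0.76
2.243	0.92	0.80
2.191	0.92	0.84
2.079	0.92	0.88
1.985	0.92	0.92
1.944	0.88	0.92
1.897	0.84	0.92
1.836	0.80	0.92
1.741	0.76	0.92
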