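# auc=0.809 n1=43 n0=117 direction=lt
cutpoint	se	sp
0.272	0.651	0.814
0.282	0.674	0.763
0.290	0.698	0.754
0.295	0.767	0.695
0.303	0.814	0.610
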