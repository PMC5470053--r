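# auc=0.647 n1=43 n0=117 direction=gt
cutpoint	se	sp
84	0.674	0.534
85	0.628	0.585
86	0.581	0.619
87	0.512	0.686
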