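# auc=0.892 n1=43 n0=117 direction=lt
cutpoint	se	sp
24	0.535	0.983
27	0.814	0.797
30	0.837	0.797
34	0.837	0.771
37	1.000	0.390
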