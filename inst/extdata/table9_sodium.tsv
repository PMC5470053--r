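# auc=0.777 n1=43 n0=117 direction=lt
cutpoint	se	sp
133	0.535	0.822
134	0.605	0.763
135	0.721	0.669
136	0.814	0.576
137	0.930	0.483
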