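mass_g,phi
0.316228,0.008176
0.630957,0.01029
1.25893,0.01296
2.51189,0.01631
5.01187,0.02054
10,0.02585
19.9526,0.03255
39.8107,0.04097
79.4328,0.05158
158.489,0.06494
316.228,0.08176
630.957,0.1029
1258.93,0.1296
2511.89,0.1631
5011.87,0.2054
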