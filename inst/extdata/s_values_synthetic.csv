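target,source,s_value_Gy_per_GBq_h
kidneys,kidneys,0.280317
kidneys,liver,0.000641904
kidneys,spleen,0.000513523
kidneys,red marrow,0.000641904
kidneys,total body,0.00151403
liver,kidneys,0.000331651
liver,liver,0.0490506
liver,spleen,0.00011055
liver,red marrow,0.000331651
liver,total body,0.00147877
spleen,kidneys,0.000663301
spleen,liver,0.000442201
spleen,spleen,0.480557
spleen,red marrow,0.000663301
spleen,total body,0.00147128
red marrow,kidneys,0.000510232
red marrow,liver,0.000680309
red marrow,spleen,0.000340154
red marrow,red marrow,0.0746121
red marrow,total body,0.00151022
total body,kidneys,0.00134545
total body,liver,0.00137615
total body,spleen,0.0013318
total body,red marrow,0.00135966
total body,total body,0.00131807
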