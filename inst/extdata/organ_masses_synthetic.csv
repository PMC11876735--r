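organ,mass_g
kidneys,310
liver,1800
spleen,180
red marrow,1170
total body,70000
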