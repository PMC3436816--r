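g0002
g0045
g0060
g0084
g0095
g0102
g0129
g0154
g0171
g0178
g0184
g0187
g0193
g0249
g0292
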