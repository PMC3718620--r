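age_group,weight
20-34,0.2929
35-44,0.2247
45-54,0.1875
55-64,0.1208
65-74,0.0915
75+,0.0826
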