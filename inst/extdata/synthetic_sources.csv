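source_id,role,A64,A66,A67,A68,A70
soil_natural,soil,49.17,27.73,4.04,18.45,0.61
compost_67_labeled,fertilizer,35.3131,19.9154,31.08,13.2504,0.4381
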