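predicted,North,South
North,74,12
South,5,26
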