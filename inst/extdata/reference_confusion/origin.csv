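predicted,German,non-German
German,112,8
non-German,5,68
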