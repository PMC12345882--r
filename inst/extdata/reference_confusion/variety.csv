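predicted,Boskoop,Braeburn,Cripps Pink,Elstar,Gala,Jonagold
Boskoop,8,0,0,1,0,0
Braeburn,0,8,0,0,1,0
Cripps Pink,0,0,12,0,0,0
Elstar,1,0,0,10,0,1
Gala,0,3,0,0,27,0
Jonagold,0,0,0,1,0,7
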