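subject,food_code,amount_g
S1,13101234,250
S1,10201001,300
S2,13102001,400
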