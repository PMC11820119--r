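food_code,name,description
13101234,"Beef, mince, <5% fat, raw",fixture food
13101235,"Beef, mince, cooked, no added fat",fixture food
11101001,"Water, tap",fixture food
14101001,"Salt, table",fixture food
13102001,"Beef casserole, homemade",fixture food
10201001,"Tea, black, brewed, plain",fixture food
13103001,"Beef casserole, takeaway",fixture food
19101001,"Echidna, wild caught, flesh, raw",fixture food
13104001,Beef dish with wild-caught meat,fixture food
13101236,"Beef, other cut",fixture food
16101001,"Apple, canned",fixture food
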