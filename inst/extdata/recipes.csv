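parent_food_code,ingredient_food_code,ingredient_weight_g
13102001,13101234,500
13102001,11101001,500
13104001,13101234,90
13104001,19101001,10
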