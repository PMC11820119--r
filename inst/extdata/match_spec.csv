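food_code,method,target,note
13101234,direct,Beef meat,NA
13101235,approximate,Beef meat,NA
11101001,direct,Water,NA
14101001,direct,Salt,NA
13102001,recipe_file,NA,NA
10201001,description_recipe,Tea leaves=15; Water=1000,NA
13103001,similar_food,13102001,NA
19101001,excluded,NA,NA
13104001,recipe_file,NA,NA
13101236,group_average,NA,NA
16101001,processing_factor,Apple fresh | fruit,NA
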