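item_name,gwp_value,source_tag
Beef meat,16.68,fixture
Salt,0.06,fixture
Water,0,fixture
Tea leaves,7.3,fixture
Apple fresh,0.5,fixture
Pear processed,0.8,fixture
Pear fresh,0.4,fixture
Bean processed,0.9,fixture
Bean fresh,0.3,fixture
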