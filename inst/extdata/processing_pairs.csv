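category,processed_item,fresh_item
fruit,Pear processed,Pear fresh
vegetable,Bean processed,Bean fresh
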