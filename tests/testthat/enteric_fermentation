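{"scenario":"ec_reference","parameter":"herd.enteric_ef","output":"enteric_fermentation","relative_delta":0.1,"mode":"replication","elasticity":1}
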