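# FLS rules
220 H FLS-FeII-binding
222 D FLS-FeII-binding
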