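((((B1,W1),B2),W2),R1);
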