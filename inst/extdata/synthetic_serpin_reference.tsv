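id	hinge_start	p1_position
SerpinREF	345	361
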