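motif	chain	start	end
L1_loop	A	157	164
L2_loop	A	195	209
LexA_binding_loop	A	229	243
thumb	B	241	300
little_finger	B	301	351
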