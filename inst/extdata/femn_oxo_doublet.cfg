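[doublet]
g = 2.042, 2.031, 2.007
A_Mn = 215, 243, 341
euler_gA = 73, 54, 76
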