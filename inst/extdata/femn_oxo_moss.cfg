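[fe]
S = 2.5
g = 2, 2, 2
[mn]
S = 2
g = 1.970, 1.980, 1.995
A_Mn = -161.25, -182.25, -255.75
A_euler = 73, 54, 76
[dimer]
J = 120
[moss]
delta = 0.53
dEQ = -1.84
eta = 0
A_Fe = -20, -20, -20
gamma = 0.3
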