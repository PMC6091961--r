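# label x y z
Fp1 0.904508 0.293893 0.309017
Fpz 0.951057 0.000000 0.309017
Fp2 0.904508 -0.293893 0.309017
F7 0.559017 0.769421 0.309017
F3 0.645416 0.433027 0.629226
Fz 0.587785 0.000000 0.809017
F4 0.645416 -0.433027 0.629226
F8 0.559017 -0.769421 0.309017
T7 0.000000 0.951057 0.309017
C3 0.000000 0.587785 0.809017
Cz 0.000000 0.000000 1.000000
C4 0.000000 -0.587785 0.809017
T8 0.000000 -0.951057 0.309017
P7 -0.559017 0.769421 0.309017
P3 -0.645416 0.433027 0.629226
Pz -0.587785 0.000000 0.809017
P4 -0.645416 -0.433027 0.629226
P8 -0.559017 -0.769421 0.309017
O1 -0.904508 0.293893 0.309017
Oz -0.951057 0.000000 0.309017
O2 -0.904508 -0.293893 0.309017
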