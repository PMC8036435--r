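element,vdw_radius,epsilon,hydrophobicity
H,1.20,0.030,0.12
C,1.70,0.100,0.36
N,1.55,0.170,-0.60
O,1.52,0.210,-0.40
F,1.47,0.061,0.22
P,1.80,0.200,0.50
S,1.80,0.250,0.60
Cl,1.75,0.300,0.65
Br,1.85,0.389,0.85
I,1.98,0.550,1.05
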