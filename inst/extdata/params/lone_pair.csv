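# Lone-pair electronegativity polynomial chi(q) = a + b q + c q^2 (eV), v1.
# Package-defined approximations; atoms without lone pairs (H, C) score 0.
element,a,b,c
N,12.32,11.20,1.00
O,15.25,13.20,1.00
F,15.50,13.90,2.30
S,10.50,9.20,1.20
P,9.50,8.50,1.00
Cl,11.30,9.70,1.40
Br,10.30,8.50,1.20
I,10.00,8.00,1.00
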