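# Pi orbital electronegativity polynomial chi(q) = a + b q + c q^2 (eV), v1.
# Package-defined approximations for atoms that can carry pi density; elements
# absent from this table take no part in the pi equalisation.
element,a,b,c
C,5.60,8.93,0.75
N,7.95,9.73,0.27
O,10.09,11.73,1.02
S,7.00,8.16,1.20
P,6.50,7.80,1.00
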