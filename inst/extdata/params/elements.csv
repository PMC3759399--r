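# Element base table, v1. mass: IUPAC 2021 standard atomic weights (rounded);
# z: atomic number; valence: default bonding valence used for implicit H;
# vdw_r: Bondi van der Waals radius (Angstrom); cov_r: covalent radius
# (Angstrom, Cordero 2008); polarizability: static atomic dipole
# polarizability (Angstrom^3, CRC values).
element,z,mass,valence,vdw_r,cov_r,polarizability
H,1,1.008,1,1.20,0.31,0.667
C,6,12.011,4,1.70,0.76,1.760
N,7,14.007,3,1.55,0.71,1.100
O,8,15.999,2,1.52,0.66,0.802
F,9,18.998,1,1.47,0.57,0.557
P,15,30.974,3,1.80,1.07,3.630
S,16,32.060,2,1.80,1.05,2.900
Cl,17,35.450,1,1.75,1.02,2.180
Br,35,79.904,1,1.85,1.20,3.050
I,53,126.904,1,1.98,1.39,5.350
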