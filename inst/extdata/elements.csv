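# Elemental reference data used throughout the package.
# Z and A: standard atomic numbers / relative atomic masses.
# I_eV: mean excitation energies in the condensed-phase convention
# commonly used in charged-particle dosimetry (Bragg additivity over
# these values reproduces I = 75.3 eV for liquid water).
symbol,Z,A,I_eV
H,1,1.0080,19.2
C,6,12.0110,81.0
N,7,14.0070,82.0
O,8,15.9990,106.0
F,9,18.9980,115.0
Na,11,22.9900,149.0
Mg,12,24.3050,156.0
Al,13,26.9820,166.0
Si,14,28.0850,173.0
P,15,30.9740,173.0
S,16,32.0600,180.0
Cl,17,35.4500,174.0
Ar,18,39.9480,188.0
K,19,39.0980,190.0
Ca,20,40.0780,191.0
Ti,22,47.8670,233.0
Fe,26,55.8450,286.0
I,53,126.9040,491.0
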