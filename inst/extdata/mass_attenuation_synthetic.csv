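# SYNTHETIC elemental mass attenuation coefficients (cm^2/g) at the
# default effective tube energies (52 keV ~ 80 kV, 63 keV ~ 120 kV,
# 68 keV ~ 135 kV).  Values come from the package parametric
# per-electron cross-section model (exact Klein-Nishina incoherent term
# plus photoelectric Z^3.62/E^3.2 and coherent Z^1.86/E^1.9 power laws,
# amplitudes anchored to water values at 60 keV); they are a plausible
# stand-in for measured tables, not measured data.
energy_keV,symbol,Z,mu_rho_cm2_g
52,H,1,0.33419917
52,C,6,0.18151881
52,N,7,0.18774982
52,O,8,0.19577438
52,F,9,0.19494711
52,Na,11,0.22331536
52,Mg,12,0.24858155
52,Al,13,0.26375025
52,Si,14,0.29881058
52,P,15,0.31983532
52,S,16,0.36501512
52,Cl,17,0.3900283
52,Ar,18,0.40879858
52,K,19,0.49290564
52,Ca,20,0.56667342
52,Ti,22,0.65514474
52,Fe,26,1.0380358
52,I,53,9.3976827
63,H,1,0.32374796
63,C,6,0.17160689
63,N,7,0.17550002
63,O,8,0.18043934
63,F,9,0.17665969
63,Na,11,0.1940832
63,Mg,12,0.21088313
63,Al,13,0.21807782
63,Si,14,0.24057772
63,P,15,0.25065499
63,S,16,0.27850755
63,Cl,17,0.28992604
63,Ar,18,0.29635768
63,K,19,0.34894395
63,Ca,20,0.39233478
63,Ti,22,0.43591777
63,Fe,26,0.64979997
63,I,53,5.2167286
68,H,1,0.31931027
68,C,6,0.1680378
68,N,7,0.1712825
68,O,8,0.17537549
68,F,9,0.17084106
68,Na,11,0.18531529
68,Mg,12,0.19982809
68,Al,13,0.20493299
68,Si,14,0.22407642
68,P,15,0.23130322
68,S,16,0.25456845
68,Cl,17,0.26247439
68,Ar,18,0.26575681
68,K,19,0.31001773
68,Ca,20,0.34545504
68,Ti,22,0.37748804
68,Fe,26,0.54754657
68,I,53,4.1395986
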