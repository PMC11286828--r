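# Material library: bulk density and elemental mass fractions.
# Human tissues follow the widely tabulated reference-tissue
# compositions used for CT stoichiometric calibration; calibration
# inserts are SYNTHETIC tissue-substitute stand-ins at nominal
# electron-density-phantom densities (vendor compositions are not
# public); *_bone_* inserts are hydroxyapatite loadings in a
# muscle-like binder; hydroxyapatite is stoichiometric Ca10(PO4)6(OH)2.
material,density_g_cm3,element,mass_fraction
water,1,H,0.1119
water,1,O,0.8881
air,0.0012,C,0.000124
air,0.0012,N,0.755268
air,0.0012,O,0.231781
air,0.0012,Ar,0.012827
lung,0.26,H,0.103
lung,0.26,C,0.105
lung,0.26,N,0.031
lung,0.26,O,0.749
lung,0.26,Na,0.002
lung,0.26,P,0.002
lung,0.26,S,0.003
lung,0.26,Cl,0.003
lung,0.26,K,0.002
adipose,0.95,H,0.114
adipose,0.95,C,0.598
adipose,0.95,N,0.007
adipose,0.95,O,0.278
adipose,0.95,Na,0.001
adipose,0.95,S,0.001
adipose,0.95,Cl,0.001
breast,1.02,H,0.106
breast,1.02,C,0.332
breast,1.02,N,0.03
breast,1.02,O,0.527
breast,1.02,Na,0.001
breast,1.02,P,0.001
breast,1.02,S,0.002
breast,1.02,Cl,0.001
muscle,1.05,H,0.102
muscle,1.05,C,0.143
muscle,1.05,N,0.034
muscle,1.05,O,0.71
muscle,1.05,Na,0.001
muscle,1.05,P,0.002
muscle,1.05,S,0.003
muscle,1.05,Cl,0.001
muscle,1.05,K,0.004
liver,1.06,H,0.102
liver,1.06,C,0.139
liver,1.06,N,0.03
liver,1.06,O,0.716
liver,1.06,Na,0.002
liver,1.06,P,0.003
liver,1.06,S,0.003
liver,1.06,Cl,0.002
liver,1.06,K,0.003
blood,1.06,H,0.102
blood,1.06,C,0.11
blood,1.06,N,0.033
blood,1.06,O,0.745
blood,1.06,Na,0.001
blood,1.06,P,0.001
blood,1.06,S,0.002
blood,1.06,Cl,0.003
blood,1.06,K,0.002
blood,1.06,Fe,0.001
brain,1.04,H,0.107
brain,1.04,C,0.145
brain,1.04,N,0.022
brain,1.04,O,0.712
brain,1.04,Na,0.002
brain,1.04,P,0.004
brain,1.04,S,0.002
brain,1.04,Cl,0.003
brain,1.04,K,0.003
skin,1.09,H,0.1
skin,1.09,C,0.204
skin,1.09,N,0.042
skin,1.09,O,0.645
skin,1.09,Na,0.002
skin,1.09,P,0.001
skin,1.09,S,0.002
skin,1.09,Cl,0.003
skin,1.09,K,0.001
eye_lens,1.07,H,0.096
eye_lens,1.07,C,0.195
eye_lens,1.07,N,0.057
eye_lens,1.07,O,0.646
eye_lens,1.07,Na,0.001
eye_lens,1.07,P,0.001
eye_lens,1.07,S,0.003
eye_lens,1.07,Cl,0.001
cartilage,1.1,H,0.096
cartilage,1.1,C,0.099
cartilage,1.1,N,0.022
cartilage,1.1,O,0.744
cartilage,1.1,Na,0.005
cartilage,1.1,P,0.022
cartilage,1.1,S,0.009
cartilage,1.1,Cl,0.003
red_marrow,1.03,H,0.105
red_marrow,1.03,C,0.414
red_marrow,1.03,N,0.034
red_marrow,1.03,O,0.439
red_marrow,1.03,P,0.001
red_marrow,1.03,S,0.002
red_marrow,1.03,Cl,0.002
red_marrow,1.03,K,0.002
red_marrow,1.03,Fe,0.001
yellow_marrow,0.98,H,0.115
yellow_marrow,0.98,C,0.644
yellow_marrow,0.98,N,0.007
yellow_marrow,0.98,O,0.231
yellow_marrow,0.98,Na,0.001
yellow_marrow,0.98,S,0.001
yellow_marrow,0.98,Cl,0.001
spongiosa,1.18,H,0.085
spongiosa,1.18,C,0.404
spongiosa,1.18,N,0.028
spongiosa,1.18,O,0.367
spongiosa,1.18,Na,0.001
spongiosa,1.18,Mg,0.001
spongiosa,1.18,P,0.034
spongiosa,1.18,S,0.002
spongiosa,1.18,Cl,0.002
spongiosa,1.18,K,0.001
spongiosa,1.18,Ca,0.074
spongiosa,1.18,Fe,0.001
cortical_bone,1.92,H,0.034
cortical_bone,1.92,C,0.155
cortical_bone,1.92,N,0.042
cortical_bone,1.92,O,0.435
cortical_bone,1.92,Na,0.001
cortical_bone,1.92,Mg,0.002
cortical_bone,1.92,P,0.103
cortical_bone,1.92,S,0.003
cortical_bone,1.92,Ca,0.225
hydroxyapatite,3.16,Ca,0.398939294097
hydroxyapatite,3.16,P,0.184990454045
hydroxyapatite,3.16,O,0.41406351096
hydroxyapatite,3.16,H,0.0020067408975
trabecular_bone_200,1.16,Ca,0.0687826369133
trabecular_bone_200,1.16,P,0.0335500782836
trabecular_bone_200,1.16,O,0.658976467407
trabecular_bone_200,1.16,H,0.0847597829134
trabecular_bone_200,1.16,C,0.118344827586
trabecular_bone_200,1.16,N,0.0281379310345
trabecular_bone_200,1.16,Na,0.000827586206897
trabecular_bone_200,1.16,S,0.00248275862069
trabecular_bone_200,1.16,Cl,0.000827586206897
trabecular_bone_200,1.16,K,0.00331034482759
dense_bone_800,1.53,Ca,0.208595709332
dense_bone_800,1.53,P,0.0976812831608
dense_bone_800,1.53,O,0.555261966515
dense_bone_800,1.53,H,0.0497159429529
dense_bone_800,1.53,C,0.0682287581699
dense_bone_800,1.53,N,0.0162222222222
dense_bone_800,1.53,Na,0.000477124183007
dense_bone_800,1.53,S,0.00143137254902
dense_bone_800,1.53,Cl,0.000477124183007
dense_bone_800,1.53,K,0.00190849673203
dense_bone_1250,1.82,Ca,0.273996767924
dense_bone_1250,1.82,P,0.127680256899
dense_bone_1250,1.82,O,0.506746916868
dense_bone_1250,1.82,H,0.033323311056
dense_bone_1250,1.82,C,0.0447857142857
dense_bone_1250,1.82,N,0.0106483516484
dense_bone_1250,1.82,Na,0.000313186813187
dense_bone_1250,1.82,S,0.00093956043956
dense_bone_1250,1.82,Cl,0.000313186813187
dense_bone_1250,1.82,K,0.00125274725275
lung_inhale,0.3,H,0.103
lung_inhale,0.3,C,0.105
lung_inhale,0.3,N,0.031
lung_inhale,0.3,O,0.749
lung_inhale,0.3,Na,0.002
lung_inhale,0.3,P,0.002
lung_inhale,0.3,S,0.003
lung_inhale,0.3,Cl,0.003
lung_inhale,0.3,K,0.002
lung_exhale,0.5,H,0.103
lung_exhale,0.5,C,0.105
lung_exhale,0.5,N,0.031
lung_exhale,0.5,O,0.749
lung_exhale,0.5,Na,0.002
lung_exhale,0.5,P,0.002
lung_exhale,0.5,S,0.003
lung_exhale,0.5,Cl,0.003
lung_exhale,0.5,K,0.002
adipose_insert,0.96,H,0.114
adipose_insert,0.96,C,0.598
adipose_insert,0.96,N,0.007
adipose_insert,0.96,O,0.278
adipose_insert,0.96,Na,0.001
adipose_insert,0.96,S,0.001
adipose_insert,0.96,Cl,0.001
breast_insert,0.99,H,0.106
breast_insert,0.99,C,0.332
breast_insert,0.99,N,0.03
breast_insert,0.99,O,0.527
breast_insert,0.99,Na,0.001
breast_insert,0.99,P,0.001
breast_insert,0.99,S,0.002
breast_insert,0.99,Cl,0.001
muscle_insert,1.06,H,0.102
muscle_insert,1.06,C,0.143
muscle_insert,1.06,N,0.034
muscle_insert,1.06,O,0.71
muscle_insert,1.06,Na,0.001
muscle_insert,1.06,P,0.002
muscle_insert,1.06,S,0.003
muscle_insert,1.06,Cl,0.001
muscle_insert,1.06,K,0.004
liver_insert,1.07,H,0.102
liver_insert,1.07,C,0.139
liver_insert,1.07,N,0.03
liver_insert,1.07,O,0.716
liver_insert,1.07,Na,0.002
liver_insert,1.07,P,0.003
liver_insert,1.07,S,0.003
liver_insert,1.07,Cl,0.002
liver_insert,1.07,K,0.003
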