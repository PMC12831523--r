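# Tissue-surrogate material table (long format).
# Composition rows carry (material, element, mass_fraction); one summary row per
# material (element empty) carries mass_density [g/cm3] and, when the
# manufacturer supplies them, the corrected RED, the effective atomic number and
# the measured RSP reference with its uncertainty.
# Compositions: published elemental analyses of the Gammex tissue-characterization
# plugs (as tabulated in the DECT/stoichiometric-calibration literature), plus
# water and two high-Z calibration anchors (hydroxyapatite, elemental calcium)
# used only to extend the Zeff -> I correlation beyond the bone range.
material,element,mass_fraction,mass_density,red_ref,zeff_ref,rsp_ref,rsp_ref_sd
water,H,0.1119,,,,,
water,O,0.8881,,,,,
water,,,1.000,1.00,7.42,1.000,0.000
lung_ln300,H,0.0846,,,,,
lung_ln300,C,0.5938,,,,,
lung_ln300,N,0.0196,,,,,
lung_ln300,O,0.1814,,,,,
lung_ln300,Mg,0.1119,,,,,
lung_ln300,Si,0.0078,,,,,
lung_ln300,Cl,0.0010,,,,,
lung_ln300,,,0.300,0.29,7.61,0.263,0.010
lung_ln450,H,0.0847,,,,,
lung_ln450,C,0.5957,,,,,
lung_ln450,N,0.0197,,,,,
lung_ln450,O,0.1811,,,,,
lung_ln450,Mg,0.1121,,,,,
lung_ln450,Si,0.0058,,,,,
lung_ln450,Cl,0.0010,,,,,
lung_ln450,,,0.450,0.44,7.58,0.459,0.006
adipose_ap6,H,0.0906,,,,,
adipose_ap6,C,0.7230,,,,,
adipose_ap6,N,0.0225,,,,,
adipose_ap6,O,0.1627,,,,,
adipose_ap6,Cl,0.0013,,,,,
adipose_ap6,,,0.943,0.93,6.14,0.939,0.003
breast_br12,H,0.0859,,,,,
breast_br12,C,0.7011,,,,,
breast_br12,N,0.0233,,,,,
breast_br12,O,0.1790,,,,,
breast_br12,Cl,0.0013,,,,,
breast_br12,Ca,0.0095,,,,,
breast_br12,,,0.980,0.96,6.82,0.976,0.003
solid_water,H,0.0802,,,,,
solid_water,C,0.6723,,,,,
solid_water,N,0.0241,,,,,
solid_water,O,0.1991,,,,,
solid_water,Cl,0.0014,,,,,
solid_water,Ca,0.0231,,,,,
solid_water,,,1.015,0.99,7.59,1.005,0.003
brain_sr2,H,0.1083,,,,,
brain_sr2,C,0.7254,,,,,
brain_sr2,N,0.0169,,,,,
brain_sr2,O,0.1486,,,,,
brain_sr2,Cl,0.0008,,,,,
brain_sr2,,,1.049,1.04,7.40,1.069,0.003
liver_lv1,H,0.0806,,,,,
liver_lv1,C,0.6701,,,,,
liver_lv1,N,0.0247,,,,,
liver_lv1,O,0.2001,,,,,
liver_lv1,Cl,0.0014,,,,,
liver_lv1,Ca,0.0231,,,,,
liver_lv1,,,1.096,1.06,7.59,1.080,0.003
inner_bone,H,0.0667,,,,,
inner_bone,C,0.5564,,,,,
inner_bone,N,0.0196,,,,,
inner_bone,O,0.2352,,,,,
inner_bone,P,0.0323,,,,,
inner_bone,Cl,0.0011,,,,,
inner_bone,Ca,0.0886,,,,,
inner_bone,,,1.133,1.09,10.11,1.090,0.003
b200,H,0.0665,,,,,
b200,C,0.5552,,,,,
b200,N,0.0198,,,,,
b200,O,0.2364,,,,,
b200,P,0.0324,,,,,
b200,Cl,0.0011,,,,,
b200,Ca,0.0887,,,,,
b200,,,1.146,1.10,10.11,1.108,0.003
cb2_30,H,0.0668,,,,,
cb2_30,C,0.5348,,,,,
cb2_30,N,0.0212,,,,,
cb2_30,O,0.2561,,,,,
cb2_30,Cl,0.0011,,,,,
cb2_30,Ca,0.1201,,,,,
cb2_30,,,1.335,1.28,10.78,1.267,0.002
cb2_50,H,0.0477,,,,,
cb2_50,C,0.4163,,,,,
cb2_50,N,0.0152,,,,,
cb2_50,O,0.3200,,,,,
cb2_50,Cl,0.0008,,,,,
cb2_50,Ca,0.2002,,,,,
cb2_50,,,1.560,1.47,12.40,1.427,0.002
cortical_sb3,H,0.0341,,,,,
cortical_sb3,C,0.3141,,,,,
cortical_sb3,N,0.0184,,,,,
cortical_sb3,O,0.3650,,,,,
cortical_sb3,Cl,0.0004,,,,,
cortical_sb3,Ca,0.2681,,,,,
cortical_sb3,,,1.822,1.69,13.53,1.616,0.005
hydroxyapatite,H,0.0020,,,,,
hydroxyapatite,O,0.4141,,,,,
hydroxyapatite,P,0.1850,,,,,
hydroxyapatite,Ca,0.3989,,,,,
hydroxyapatite,,,3.160,,,,
calcium,Ca,1.0000,,,,,
calcium,,,1.550,,,,
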