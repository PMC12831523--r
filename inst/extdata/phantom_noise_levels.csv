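# Image noise (standard deviation of a central circular ROI) in the effective
# atomic number, relative electron density and derived RSP maps, as a function
# of phantom size and CTDIvol. The measurement circle is 2.8 cm in diameter at
# the phantom center; for aed_head the center holds a solid-water insert, so a
# 1 cm circle inside that insert is used instead.
# key = <phantom>_<CTDIvol>, used to select a noise preset when simulating.
key,phantom,diameter_cm,ctdi_mgy,sigma_zeff,sigma_red,sigma_rsp,roi_diameter_cm
aed_body_18.85,aed_body,34.6,18.85,0.636,0.023,0.018,2.8
aed_head_18.85,aed_head,20,18.85,0.153,0.008,0.008,1.0
aed_head_82.77,aed_head,20,82.77,0.087,0.004,0.004,1.0
model467_14.55,model467,33,14.55,0.496,0.021,0.018,2.8
model467_82.77,model467,33,82.77,0.223,0.011,0.010,2.8
george_body_18.85,george_body,27,18.85,0.382,0.010,0.007,2.8
george_head_18.85,george_head,18,18.85,0.240,0.007,0.006,2.8
george_head_82.77,george_head,18,82.77,0.028,0.003,0.003,2.8
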