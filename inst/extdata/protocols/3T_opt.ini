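# Optimized 3T T2-weighted DANTE-SPACE protocol (homogeneous B1 assumed at 3T)
[protocol]
label = 3T_opt
field_t = 3T
b1_mode = homogeneous
b1_scale_prep = 1.0
b1_scale_readout = 1.0
[dante]
flip_deg = 12
n_pulses = 250
interpulse_ms = 1.0
grad_mT_m = 80
grad_dur_ms = 0.5
rf_phase_schedule = constant
[space]
tr_s = 2.10
echo_spacing_ms = 5.0
etl = 59
te_eq_ms = 165
excitation_deg = 90
[sat]
slab_mm = 70
gap_mm = 0
delay_ms = 5
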