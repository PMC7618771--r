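# Optimized 7T protocol with a neck-and-CoW RF shim during DANTE
[protocol]
label = 7T_shim
field_t = 7T
b1_mode = shim
b1_scale_prep = 0.75
b1_scale_readout = 1.0
[dante]
flip_deg = 12
n_pulses = 170
interpulse_ms = 1.0
grad_mT_m = 70
grad_dur_ms = 0.5
rf_phase_schedule = constant
[space]
tr_s = 2.62
echo_spacing_ms = 4.62
etl = 74
te_eq_ms = 165
excitation_deg = 90
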