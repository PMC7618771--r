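# 7T literature protocol: SPACE settings only. The literature DANTE values
# were never published; set them before simulating with this preset.
[protocol]
label = 7T_lit
field_t = 7T
b1_mode = CP
b1_scale_prep = 0.5
b1_scale_readout = 1.0
[dante]
flip_deg = NA
n_pulses = NA
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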