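name,field_t,t1_ms,t2_ms,mean_speed_cm_s,diffusion_mm2_s
vw,3T,1227,55,0.054,0
csf,3T,4019,517,0.367,0.003
blood,3T,1779,122,24.0,0.003
vw,7T,1628,46,0.054,0
csf,7T,4019,311,0.367,0.003
blood,7T,2290,100,24.0,0.003
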