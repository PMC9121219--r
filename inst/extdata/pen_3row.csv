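t_s,x_mm,y_mm,pressure,incl_h_deg,incl_v_deg,hover_mm
0,10,20,0.5,170,60,0
0.0055555556,10.1,20.05,0.52,170.5,60.2,0
0.0111111111,10.2,20.1,0,171,60.4,1.5
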