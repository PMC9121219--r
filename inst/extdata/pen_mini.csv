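t_s,x_mm,y_mm,pressure,incl_h_deg,incl_v_deg,hover_mm
0,10,20,0.5,170,60,0
0.0055555556,10.3,20.4,0.52,170.5,60.2,0
0.0111111111,10.6,20.8,0.54,171,60.4,0
0.0166666667,10.9,21.2,0.5,171.5,60.6,0
0.0222222222,11.2,21.6,0,172,60.8,1.5
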