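label,alpha_beta_gy,se_gy,endpoint,strain,followup
synthetic study 01,3.1,0.6,breathing rate,C57BL/6,24w
synthetic study 02,4.2,1.1,LD50,CBA,36w
synthetic study 03,5.3,0.9,breathing rate,C3H,28w
synthetic study 04,2.8,1.5,histology,C57BL/6,26w
synthetic study 05,4.9,0.7,breathing rate,CBA,52w
synthetic study 06,3.6,0.5,CT density,C57BL/6,24w
synthetic study 07,6.1,2.2,LD50,C3H,30w
synthetic study 08,4.4,0.8,breathing rate,CBA/Ca,40w
synthetic study 09,3.9,1.0,pneumonitis,C57BL/6,16w
synthetic study 10,5.6,1.8,LD50,C3Hf/Kam,36w
synthetic study 11,4.0,0.9,breathing rate,WHT,28w
synthetic study 12,3.4,1.3,CT density,C57BL/6,24w
synthetic study 13,4.7,1.2,histology,CBA,32w
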