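point_name,x,y,z
medial_plateau_contact,-18.675,0,141.1
lateral_plateau_contact,15.687,0,141.1
tibial_tuberosity,0,18,111.1
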