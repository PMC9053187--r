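name,x,y,z
hip_center,0,0,547.8
knee_center,0,0,141.1
plateau_medial,-37.35,0,141.1
plateau_lateral,37.35,0,141.1
ankle_center,0,0,-224.1
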