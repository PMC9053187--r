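step,activity,instance,point_name,fx,fy,fz
1,ACT1,1,medial_plateau_contact,-0.0743,0.0297,-1.4858
1,ACT1,1,lateral_plateau_contact,-0.0455,0.0182,-0.9107
1,ACT1,1,tibial_tuberosity,0,0.1506,0.4768
2,ACT1,2,medial_plateau_contact,-0.0867,0.0347,-1.7335
2,ACT1,2,lateral_plateau_contact,-0.0531,0.0212,-1.0625
2,ACT1,2,tibial_tuberosity,0,0.2108,0.6675
3,ACT1,3,medial_plateau_contact,-0.0929,0.0371,-1.8573
3,ACT1,3,lateral_plateau_contact,-0.0569,0.0228,-1.1384
3,ACT1,3,tibial_tuberosity,0,0.2409,0.7629
4,ACT1,4,medial_plateau_contact,-0.0805,0.0322,-1.6097
4,ACT1,4,lateral_plateau_contact,-0.0493,0.0197,-0.9866
4,ACT1,4,tibial_tuberosity,0,0.1807,0.5721
5,ACT1,5,medial_plateau_contact,-0.0681,0.0272,-1.362
5,ACT1,5,lateral_plateau_contact,-0.0417,0.0167,-0.8348
5,ACT1,5,tibial_tuberosity,0,0.1506,0.4768
6,ACT2,1,medial_plateau_contact,-0.1022,0.0409,-2.043
6,ACT2,1,lateral_plateau_contact,-0.0626,0.025,-1.2522
6,ACT2,1,tibial_tuberosity,0,0.3614,1.1443
7,ACT2,2,medial_plateau_contact,-0.1083,0.0433,-2.1669
7,ACT2,2,lateral_plateau_contact,-0.0664,0.0266,-1.3281
7,ACT2,2,tibial_tuberosity,0,0.4517,1.4304
8,ACT2,3,medial_plateau_contact,-0.0991,0.0396,-1.9811
8,ACT2,3,lateral_plateau_contact,-0.0607,0.0243,-1.2142
8,ACT2,3,tibial_tuberosity,0,0.4216,1.335
9,ACT2,4,medial_plateau_contact,-0.0929,0.0371,-1.8573
9,ACT2,4,lateral_plateau_contact,-0.0569,0.0228,-1.1384
9,ACT2,4,tibial_tuberosity,0,0.3312,1.0489
10,ACT2,5,medial_plateau_contact,-0.1052,0.0421,-2.105
10,ACT2,5,lateral_plateau_contact,-0.0645,0.0258,-1.2901
10,ACT2,5,tibial_tuberosity,0,0.3915,1.2397
11,ACT3,1,medial_plateau_contact,-0.1052,0.0421,-2.105
11,ACT3,1,lateral_plateau_contact,-0.0645,0.0258,-1.2901
11,ACT3,1,tibial_tuberosity,0,0.3915,1.2397
12,ACT3,2,medial_plateau_contact,-0.1176,0.0471,-2.3526
12,ACT3,2,lateral_plateau_contact,-0.0721,0.0288,-1.4419
12,ACT3,2,tibial_tuberosity,0,0.4818,1.5257
13,ACT3,3,medial_plateau_contact,-0.1114,0.0446,-2.2288
13,ACT3,3,lateral_plateau_contact,-0.0683,0.0273,-1.366
13,ACT3,3,tibial_tuberosity,0,0.4517,1.4304
14,ACT3,4,medial_plateau_contact,-0.0991,0.0396,-1.9811
14,ACT3,4,lateral_plateau_contact,-0.0607,0.0243,-1.2142
14,ACT3,4,tibial_tuberosity,0,0.3614,1.1443
15,ACT3,5,medial_plateau_contact,-0.0929,0.0371,-1.8573
15,ACT3,5,lateral_plateau_contact,-0.0569,0.0228,-1.1384
15,ACT3,5,tibial_tuberosity,0,0.3312,1.0489
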