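pcg,group,noise_db,method,value
Normal (13Y),normal,5,vwg,0.0266
Normal (13Y),normal,5,vgw,0.0269
Normal (13Y),normal,5,wst,0.0531
Normal (13Y),normal,5,vmd_last,0.0317
Normal (13Y),normal,10,vwg,0.0145
Normal (13Y),normal,10,vgw,0.0146
Normal (13Y),normal,10,wst,0.0318
Normal (13Y),normal,10,vmd_last,0.0996
Normal (4Y),normal,5,vwg,0.0277
Normal (4Y),normal,5,vgw,0.0286
Normal (4Y),normal,5,wst,0.0486
Normal (4Y),normal,5,vmd_last,0.0735
Normal (4Y),normal,10,vwg,0.0157
Normal (4Y),normal,10,vgw,0.0156
Normal (4Y),normal,10,wst,0.0315
Normal (4Y),normal,10,vmd_last,0.0807
Normal (1Y),normal,5,vwg,0.0314
Normal (1Y),normal,5,vgw,0.0315
Normal (1Y),normal,5,wst,0.0475
Normal (1Y),normal,5,vmd_last,0.0380
Normal (1Y),normal,10,vwg,0.0187
Normal (1Y),normal,10,vgw,0.0183
Normal (1Y),normal,10,wst,0.0311
Normal (1Y),normal,10,vmd_last,0.0599
Normal (7Y),normal,5,vwg,0.0274
Normal (7Y),normal,5,vgw,0.0275
Normal (7Y),normal,5,wst,0.0483
Normal (7Y),normal,5,vmd_last,0.0287
Normal (7Y),normal,10,vwg,0.0152
Normal (7Y),normal,10,vgw,0.0151
Normal (7Y),normal,10,wst,0.0307
Normal (7Y),normal,10,vmd_last,0.0849
VSD (2Y),pathological,5,vwg,0.0467
VSD (2Y),pathological,5,vgw,0.0465
VSD (2Y),pathological,5,wst,0.0769
VSD (2Y),pathological,5,vmd_last,0.0518
VSD (2Y),pathological,10,vwg,0.0377
VSD (2Y),pathological,10,vgw,0.0364
VSD (2Y),pathological,10,wst,0.0550
VSD (2Y),pathological,10,vmd_last,0.0931
ASD (4Y),pathological,5,vwg,0.0454
ASD (4Y),pathological,5,vgw,0.0509
ASD (4Y),pathological,5,wst,0.0823
ASD (4Y),pathological,5,vmd_last,0.1049
ASD (4Y),pathological,10,vwg,0.0377
ASD (4Y),pathological,10,vgw,0.0383
ASD (4Y),pathological,10,wst,0.0573
ASD (4Y),pathological,10,vmd_last,0.1109
ECD (4Y),pathological,5,vwg,0.0387
ECD (4Y),pathological,5,vgw,0.0379
ECD (4Y),pathological,5,wst,0.0756
ECD (4Y),pathological,5,vmd_last,0.0950
ECD (4Y),pathological,10,vwg,0.0373
ECD (4Y),pathological,10,vgw,0.0359
ECD (4Y),pathological,10,wst,0.0547
ECD (4Y),pathological,10,vmd_last,0.0953
PDA (6Y),pathological,5,vwg,0.0431
PDA (6Y),pathological,5,vgw,0.0350
PDA (6Y),pathological,5,wst,0.0512
PDA (6Y),pathological,5,vmd_last,0.0581
PDA (6Y),pathological,10,vwg,0.0403
PDA (6Y),pathological,10,vgw,0.0353
PDA (6Y),pathological,10,wst,0.0359
PDA (6Y),pathological,10,vmd_last,0.0697
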