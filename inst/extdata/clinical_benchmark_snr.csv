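pcg,group,noise_db,method,value
Normal (13Y),normal,5,vwg,15.61
Normal (13Y),normal,5,vgw,15.85
Normal (13Y),normal,5,wst,9.38
Normal (13Y),normal,5,vmd_last,13.06
Normal (13Y),normal,10,vwg,19.32
Normal (13Y),normal,10,vgw,19.42
Normal (13Y),normal,10,wst,12.61
Normal (13Y),normal,10,vmd_last,3.13
Normal (4Y),normal,5,vwg,13.92
Normal (4Y),normal,5,vgw,13.88
Normal (4Y),normal,5,wst,8.55
Normal (4Y),normal,5,vmd_last,4.63
Normal (4Y),normal,10,vwg,16.43
Normal (4Y),normal,10,vgw,16.74
Normal (4Y),normal,10,wst,11.68
Normal (4Y),normal,10,vmd_last,3.82
Normal (1Y),normal,5,vwg,13.30
Normal (1Y),normal,5,vgw,13.55
Normal (1Y),normal,5,wst,9.88
Normal (1Y),normal,5,vmd_last,11.65
Normal (1Y),normal,10,vwg,17.28
Normal (1Y),normal,10,vgw,17.43
Normal (1Y),normal,10,wst,13.34
Normal (1Y),normal,10,vmd_last,7.68
Normal (7Y),normal,5,vwg,14.76
Normal (7Y),normal,5,vgw,15.46
Normal (7Y),normal,5,wst,10.20
Normal (7Y),normal,5,vmd_last,14.38
Normal (7Y),normal,10,vwg,19.69
Normal (7Y),normal,10,vgw,19.86
Normal (7Y),normal,10,wst,13.67
Normal (7Y),normal,10,vmd_last,4.94
VSD (2Y),pathological,5,vwg,8.81
VSD (2Y),pathological,5,vgw,8.22
VSD (2Y),pathological,5,wst,4.13
VSD (2Y),pathological,5,vmd_last,7.25
VSD (2Y),pathological,10,vwg,9.19
VSD (2Y),pathological,10,vgw,9.49
VSD (2Y),pathological,10,wst,6.27
VSD (2Y),pathological,10,vmd_last,2.17
ASD (4Y),pathological,5,vwg,11.49
ASD (4Y),pathological,5,vgw,11.27
ASD (4Y),pathological,5,wst,6.45
ASD (4Y),pathological,5,vmd_last,4.08
ASD (4Y),pathological,10,vwg,13.71
ASD (4Y),pathological,10,vgw,13.68
ASD (4Y),pathological,10,wst,9.53
ASD (4Y),pathological,10,vmd_last,3.60
ECD (4Y),pathological,5,vwg,12.86
ECD (4Y),pathological,5,vgw,12.83
ECD (4Y),pathological,5,wst,6.59
ECD (4Y),pathological,5,vmd_last,4.69
ECD (4Y),pathological,10,vwg,13.92
ECD (4Y),pathological,10,vgw,13.77
ECD (4Y),pathological,10,wst,9.58
ECD (4Y),pathological,10,vmd_last,4.67
PDA (6Y),pathological,5,vwg,6.75
PDA (6Y),pathological,5,vgw,8.02
PDA (6Y),pathological,5,wst,5.30
PDA (6Y),pathological,5,vmd_last,4.09
PDA (6Y),pathological,10,vwg,7.37
PDA (6Y),pathological,10,vgw,8.89
PDA (6Y),pathological,10,wst,8.40
PDA (6Y),pathological,10,vmd_last,2.52
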