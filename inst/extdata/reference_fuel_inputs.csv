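strain,adu,lcsf
WS,1.47,6.69
M1,1.23,7.40
M2,1.07,8.59
M4,1.20,7.61
M5,1.27,7.62
M8,0.87,11.23
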