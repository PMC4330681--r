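species,C,HE,N,P,pH,S
Anthyllis vulneraria L.,3,3,2,2.9,7,0
Lotus corniculatus L.,3,7,4,0.0,7,4
Medicago lupulina L.,NA,4,NA,3.8,8,0
Medicago sativa L.,7,3,NA,10.0,9,0
Melilotus albus Medik.,6,3,4,NA,7,0
Onobrychis viciifolia Scop.,6,3,3,4.0,8,0
Securigera varia L. (Lassen),5,4,3,NA,9,0
Trifolium campestre Schreb.,3,4,3,4.6,6,0
Trifolium fragiferum L.,5,7,7,8.2,8,4
Trifolium pratense L.,3,5,NA,0,6,0
Trifolium repens L.,NA,5,6,0,6,1
Vicia cracca L.,NA,6,NA,3.8,NA,1
Vicia tenuifolia Roth.,6,3,2,8.3,8,0
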