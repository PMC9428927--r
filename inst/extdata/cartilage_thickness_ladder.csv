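# Comparative articular-cartilage thickness ladder for the hip joint,
# applied to a 289 mm femur. Sources: minimum/average/maximum thickness of
# human and chimpanzee comparative specimens, scaled by femoral length.
simulation,thickness_mm,source
1,0.764,minimum human thickness
2,1.183,minimum chimpanzee thickness
3,1.951,average human thickness
4,2.587,maximum human thickness
5,3.069,average chimpanzee thickness
6,5.321,maximum chimpanzee thickness
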