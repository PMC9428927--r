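# Reference four-DOF hip ROM simulation summaries (viable poses on the
# default 5-degree grid; alpha-shape volume of the cosine-corrected cloud).
# Simulations 1-6: a small hominin hip at increasing joint spacing;
# 7: modern human; 8: modern chimpanzee. Used by the worked examples and
# the acceptance script as inputs to volume-ratio reports.
simulation,specimen,viable_poses,volume_deg3
1,hominin,9758,1048249
2,hominin,14890,1645521
3,hominin,32021,3652600
4,hominin,35655,4014458
5,hominin,36345,4062729
6,hominin,36476,4075208
7,human,32924,4000521
8,chimpanzee,48218,5632700
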