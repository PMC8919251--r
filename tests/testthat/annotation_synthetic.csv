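gene_id,go_category,class
g0001,positive regulation of cell death,antiproliferative
g0002,negative regulation of cell cycle,antiproliferative
g0003,positive regulation of senescence,antiproliferative
g0004,negative regulation of cell cycle,antiproliferative
g0005,positive regulation of cell death,antiproliferative
g0006,DNA repair,other
g0007,autophagy,other
g0008,metabolic process,other
g0009,signal transduction,other
g0010,DNA repair,other
g0011,protein ubiquitination,other
g0012,metabolic process,other
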