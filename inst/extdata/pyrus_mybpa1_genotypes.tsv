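group	pool	n_hom_no_ins	n_het	n_hom_ins
P. bretschneideri	Asia_cultivated	0	1	35
P. pyrifolia	Asia_cultivated	5	26	130
P. ussuriensis	Asia_cultivated	0	2	26
P. sinkiangensis	Asia_cultivated	0	6	19
P. betulifolia	Asia_wild	5	1	1
P. calleryana	Asia_wild	4	0	1
P. pashia	Asia_wild	0	1	1
P. communis	Europe_cultivated	0	0	49
P. cordata	Europe_wild	0	0	2
P. cossonii	Europe_wild	0	0	2
P. spinosa	Europe_wild	0	0	2
P. mamorensis	Europe_wild	0	0	1
P. nivalis	Europe_wild	0	0	1
P. pyraster	Europe_wild	0	0	2
P. salicifolia	Europe_wild	0	0	2
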