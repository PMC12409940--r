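group	pool	n_hom_no_ins	n_het	n_hom_ins
M. domestica	cultivated	1	4	359
M. sieversii	wild	6	12	3
M. sylvestris	wild	3	1	0
M. micromalus	wild	2	5	1
M. asiatica	wild	0	2	0
M. prunifolia	wild	1	3	0
M. floribunda	wild	0	1	0
M. spectabilis	wild	0	6	1
M. baccata	wild	9	7	0
M. rockii	wild	2	1	0
M. mandshurica	wild	1	0	0
M. robusta	wild	2	6	0
M. hupehensis	wild	2	0	0
M. pinyiensis	wild	1	0	0
M. sikkimensis	wild	1	0	0
M. sieboldii	wild	3	3	0
M. komarovii	wild	0	2	0
M. kansuensis	wild	1	0	0
M. toringoides	wild	3	1	0
M. xiaojinensis	wild	1	0	0
M. honanensis	wild	1	1	0
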