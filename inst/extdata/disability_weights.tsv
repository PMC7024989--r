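cause_group	disease_area	weight
maternal	rmnch	0.30
neonatal	rmnch	0.20
post_neonatal	rmnch	0.15
stillbirth	rmnch	0.00
ncd	ncd	0.25
cancer	cancer	0.45
tb	tb	0.33
hiv	hiv	0.27
ntd	ntd	0.12
other	other	0.20
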