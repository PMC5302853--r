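phrase	lemma	score
running	A_RUN	8
watching tv	A_TV	1
skiing	A_SKI	7
walking	A_WALK	3.5
laying down	A_LAY	1
rock climbing	A_CLIMB	7.5
talking on the phone	A_PHONE	1.5
knitting	A_KNIT	1.3
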