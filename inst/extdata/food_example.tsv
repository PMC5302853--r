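phrase	lemma	score
pizza	F_PIZZA	266
apples	F_APPLE	52
ice cream	F_ICECREAM	207
grilled chicken	F_CHICKEN	165
donuts	F_DONUT	452
mash potatoes	F_MASHPOT	83
green beans	F_GREENBEAN	31
cake with frosting	F_CAKE	367
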