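screen	category	count
hpo_egg_laying	rnai_unavailable	12
hpo_egg_laying	primary_filter	190
hpo_egg_laying	no_effect	214
hpo_egg_laying	negative_effect	48
hpo_egg_laying	positive_effect	11
egg_laying	rnai_unavailable	0
egg_laying	no_effect	224
egg_laying	negative_effect	44
egg_laying	positive_effect	5
hpo_ovariole	rnai_unavailable	0
hpo_ovariole	no_effect	206
hpo_ovariole	negative_effect	54
hpo_ovariole	positive_effect	13
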