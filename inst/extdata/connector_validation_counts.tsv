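sub_network	connectors_predicted	connectors_tested	positive_in_own_screen
core	10	10	1
hpo_egg_laying	18	17	7
egg_laying	11	11	0
hpo_ovariole	11	11	3
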