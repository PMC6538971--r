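variable	factor	loading
neonatal_mass_g	output	0.577
litter_size	output	0.577
gestation_length_d	output	0.577
interbirth_interval_d	timing	0.577
weaning_age_d	timing	0.577
sexual_maturity_d	timing	0.577
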