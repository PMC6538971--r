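species,adult_mass_g,neonatal_mass_g,litter_size,gestation_length_d,interbirth_interval_d,weaning_age_d,sexual_maturity_d
synthetic_rodent_small,35,2.1,5.5,21,60,25,55
synthetic_rodent_medium,450,9.8,4.0,30,120,35,130
synthetic_sciurid_alpine,4500,29,3.5,33,365,40,1095
synthetic_lagomorph,1800,45,5.0,31,90,26,180
synthetic_carnivore_small,4200,95,3.8,63,365,70,365
synthetic_ungulate,250000,18000,1.0,280,400,180,900
synthetic_primate_small,900,60,1.2,140,365,120,800
synthetic_primate_large,55000,1900,1.0,230,1200,450,3000
synthetic_cetacean,150000000,800000,1.0,360,900,240,3300
synthetic_chiropteran,22,4.5,1.1,55,365,45,300
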