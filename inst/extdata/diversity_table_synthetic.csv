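species,pi_s,propagule_cm,pin_pis
synthetic_nematode,0.02,0.05,0.05
synthetic_insect,0.015,0.2,0.07
synthetic_mollusc,0.008,0.1,0.09
synthetic_fish_small,0.006,0.4,0.10
synthetic_amphibian,0.003,1.0,0.12
synthetic_reptile,0.0015,5,0.15
synthetic_bird,0.0009,12,0.18
synthetic_rodent,0.0020,3,0.14
synthetic_ungulate,0.0006,60,0.22
synthetic_large_mammal,0.0003,90,0.30
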