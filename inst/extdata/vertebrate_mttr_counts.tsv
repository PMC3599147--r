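category	n_species	n_species_with_trs	n_trs	n_cr	n_3prime	n_5prime
Pisces	932	313	610	490	156	316
Amphibia	110	86	240	157	59	64
Reptilia	172	126	526	476	290	84
Aves	155	98	229	197	144	28
Mammalia	357	230	506	440	280	99
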