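# Reference set of orthologous intronic regions from non-ADH1 genes (plus
# ADH4 introns 6-8), retained after screening for LCNS, telomere proximity
# and GC content. Mean +/- sd of pairwise distances among clade pairs:
# NWM vs catarrhines, OWM vs hominoids, strepsirhines vs haplorhines.
gene	gc_pct	length	nwm_catarrhine_mean	nwm_catarrhine_sd	owm_hominoid_mean	owm_hominoid_sd	strep_haplorhine_mean	strep_haplorhine_sd
ABCA	38.1	495	0.105	0.010	0.065	0.011	0.225	0.016
CFTR_A	37.2	598	0.083	0.015	0.061	0.003	0.235	0.031
CFTR_B	37.2	511	0.116	0.012	0.045	0.006	0.215	0.028
FGA	38.2	589	0.117	0.008	0.056	0.004	0.212	0.013
ADH4_intron6	38.5	1392	0.113	0.005	0.064	0.006	0.297	0.016
ADH4_intron7	38.5	1598	0.123	0.003	0.069	0.004	0.331	0.011
ADH4_intron8	38.5	1409	0.114	0.005	0.058	0.004	0.291	0.012
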