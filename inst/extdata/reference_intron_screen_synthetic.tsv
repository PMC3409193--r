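# Screening metadata for candidate reference introns. GC percentages and
# telomere distances for the excluded loci are the published values; the
# retained loci's telomere distances (and the LCNS loci's GC values) were
# not published and carry SYNTHETIC mid-arm placeholders (50 Mbp / 39%).
gene	gc_pct	telomere_mbp	lcns	in_mrna
ABCA	38.1	50	FALSE	FALSE
CFTR_A	37.2	50	FALSE	FALSE
CFTR_B	37.2	50	FALSE	FALSE
FGA	38.2	50	FALSE	FALSE
ADH4_intron6	38.5	50	FALSE	FALSE
ADH4_intron7	38.5	50	FALSE	FALSE
ADH4_intron8	38.5	50	FALSE	FALSE
ADH1B_introns1_5	38.5	50	FALSE	TRUE
vWF	47.0	6.2	FALSE	FALSE
SREBF2	49.5	9.0	FALSE	FALSE
NRAMP	47.1	50	FALSE	FALSE
ERC2	39	50	TRUE	FALSE
LUC7	39	50	TRUE	FALSE
TTR	39	50	TRUE	FALSE
LRPPRC_A	39	50	TRUE	FALSE
LRPPRC_B	39	50	TRUE	FALSE
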