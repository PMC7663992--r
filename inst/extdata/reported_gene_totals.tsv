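species	receptor_class	n_genes	n_selected	species_design	n_comparisons
E_cornigera	SR	68	6	fed_vs_starvation	2
E_cornigera	TSR	53	1	fed_vs_starvation	2
E_timida	SR	40	6	fed_vs_starvation	3
E_timida	TSR	52	1	fed_vs_starvation	3
E_chlorotica	SR	33	4	staged_juvenile	3
E_chlorotica	TSR	40	2	staged_juvenile	3
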