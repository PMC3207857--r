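# Published inputs for the footprint relative-rate estimator: fixed
# substitutions and base counts (or base fractions, PHYLO) inside and
# outside the annotated regions.
element	method	subs_in	subs_out	bases_in	bases_out
RCPE	DNASE	24	57	144	252
ZE	DNASE	18	20	128	233
RCPE	PHYLO	195	182	0.65	0.35
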