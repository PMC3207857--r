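# Published inputs for the equilibrium relative-rate estimator:
# gain-or-loss and site-changing fixed substitution counts, total fixed
# substitutions, and the cross-species mean TFBS base fraction.
element	n_gain_plus_loss	n_change	total_fixed	frac_tfbs
RCPE	68	42	458	0.1191
ZE	22	7	84	0.1855
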