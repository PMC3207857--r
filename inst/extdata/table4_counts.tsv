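# Published 2x2 McDonald-Kreitman contingency counts for the ftz proximal-enhancer
# region (RCPE) and zebra element (ZE), one row per class, with the printed
# two-tailed Fisher exact P for each table (NA where the source prints none).
# MATCH_CORE rows are the parenthesised core-only counts of the MATCH tables.
element	method	class	fixed	poly	printed_p
RCPE	PATCH	TFBS	110	27	0.415
RCPE	PATCH	NTFBS	348	106	0.415
RCPE	PATCH_TURNOVER	making	27	11	0.460
RCPE	PATCH_TURNOVER	destroying	41	11	0.460
RCPE	PATCH_TURNOVER	other_change	42	5	NA
RCPE	MATCH	TFBS	283	84	0.839
RCPE	MATCH	NTFBS	175	49	0.839
RCPE	MATCH_CORE	TFBS	123	31	0.435
RCPE	MATCH_CORE	NTFBS	335	102	0.435
RCPE	DNASE	TFBS	24	6	0.528
RCPE	DNASE	NTFBS	57	16	0.528
RCPE	COMBINED	TFBS	300	89	0.836
RCPE	COMBINED	NTFBS	158	44	0.836
RCPE	PHYLO	TFBS	195	61	1
RCPE	PHYLO	NTFBS	182	57	1
ZE	PATCH	TFBS	29	7	0.807
ZE	PATCH	NTFBS	55	17	0.807
ZE	PATCH_TURNOVER	making	3	1	1
ZE	PATCH_TURNOVER	destroying	19	5	1
ZE	PATCH_TURNOVER	other_change	7	1	NA
ZE	MATCH	TFBS	31	10	0.812
ZE	MATCH	NTFBS	53	14	0.812
ZE	MATCH_CORE	TFBS	13	4	1
ZE	MATCH_CORE	NTFBS	71	20	1
ZE	DNASE	TFBS	18	2	0.160
ZE	DNASE	NTFBS	20	7	0.160
ZE	COMBINED	TFBS	47	14	1
ZE	COMBINED	NTFBS	37	10	1
ZE	PHYLO	TFBS	45	8	0.288
ZE	PHYLO	NTFBS	29	10	0.288
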