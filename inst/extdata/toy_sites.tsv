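# Synthetic exact-site library (factor <TAB> site); toy stand-in for a
# curated insect TFBS collection, matching toy_motif_library().
eve	TTCGAA
ftz	GGATTA
cad	TTTATG
ttk	AGGATAA
gaga	GAGAG
hb	CATAAAAA
en	TAATTG
bcd	GGGATTAG
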