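# Restriction enzymes screened for the SHELL CAPS assay (REBASE-format data).
# cut_top/cut_bottom: bases from the 5' end of the recognition site to the cut
# on each strand; offsets beyond the site length mark downstream (type IIS)
# cutters, e.g. MboII GAAGA(8/7) -> cut_top 13, cut_bottom 12.
name	site	cut_top	cut_bottom
HindIII	AAGCTT	1	5
BseMII	CTCAG	15	13
MboII	GAAGA	13	12
EcoP15I	CAGCAG	31	33
NaeI	GCCGGC	3	3
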