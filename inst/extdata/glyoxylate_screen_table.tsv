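species	n_strains_tested	growth	n_genomes	isocitrate_lyase	malate_synthase
A. fabarum	4	+	1	No	No
A. lovaniensis	1	+	0	?	?
A. ghanensis	3	-	1	No	No
A. syzygii	1	-	0	?	?
A. pasteurianus	7	-	3	No	No
A. pomorum	1	-	1	No	No
A. peroxydans	2	+	0	?	?
A. indonesiensis	2	-	1	No	No
A. orientalis	1	-	1	No	No
A. cibinongensis	1	w	1	No	No
A. tropicalis	2	-	2	No	No
A. senegalensis	3	+	2	No	No
A. orleanensis	4	-	2	No	No
A. malorum	1	-	2	No	No
A. cerevisiae	4	-	2	No	No
A. nitrogenifigens	1	+	1	Yes	Yes
A. oeni	1	-	0	?	?
A. aceti	4	+	2	Yes	Yes
A. estunensis	3	+	0	?	?
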