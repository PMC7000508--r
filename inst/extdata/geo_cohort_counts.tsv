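accession	platform	n_patients	n_pcr	n_er_pos_her2_neg	n_pcr_er_pos_her2_neg
GSE20271	Affymetrix HG-U133A	178	26	89	6
GSE20194	Affymetrix HG-U133A	278	56	140	7
GSE32646	Affymetrix HG-U133 Plus 2.0	115	27	55	5
GSE41998	Affymetrix HG-U133A 2.0	279	69	93	10
GSE25066	Affymetrix HG-U133A	486	91	268	27
GSE34138	Illumina HumanWG-6 v3	178	28	119	4
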