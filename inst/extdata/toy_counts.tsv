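contig	group	family	count
c_plp	toxin	pilosulin-like	8870
c_ick	toxin	ICK-like	90
c_pla2	toxin	phospholipase A2-like	40
c_ribo	non_toxin	ribosomal protein	3100
c_vitel	non_toxin	vitellogenin	1400
c_unk1	unidentified	NA	1900
c_unk2	unidentified	NA	600
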