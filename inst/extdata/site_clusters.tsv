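protein_id	start	end	cluster_id	cluster_name	note
beta3	294	294	1	beta3(+)/alpha1(-) intersubunit	KK202-labeled L294, faces the intersubunit cleft
beta3	308	309	1	beta3(+)/alpha1(-) intersubunit	KK200-labeled G308/R309 at the TM3 / M3-M4 loop junction
alpha1	408	408	2	alpha1 intrasubunit	KK200-labeled N408 on the C-terminal end of TM4
alpha1	415	415	2	alpha1 intrasubunit	KK123-labeled Y415 at the C-terminus of TM4
beta3	278	280	3	beta3 intrasubunit	KK202-labeled VKA278-280 on the TM2-TM3 loop; an alternative numbering of this segment as 226-228 circulates and is not used here
beta3	442	442	3	beta3 intrasubunit	KK123-labeled Y442 at the C-terminal end of TM4
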