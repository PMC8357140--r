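journal	articles_with_gene_lists	affected_articles
Nat Commun	920	345
PLoS One	946	244
Sci Rep	767	227
BMC Genomics	660	166
PLoS Genet	448	134
Oncotarget	326	107
Front Genet	313	94
eLife	243	89
Proc Natl Acad Sci USA	155	73
Cell Rep	158	71
Genome Biol	193	66
Nature	118	52
Nat Genet	140	48
Genome Med	137	44
PeerJ	137	39
Cell	74	39
Clin Epigenetics	109	38
Nucleic Acids Res	120	36
BMC Med Genomics	117	31
Front Oncol	85	31
Transl Psychiatry	73	29
BMC Cancer	105	28
PLoS Pathog	80	27
Commun Biol	74	27
PLoS Biol	66	26
Aging	56	26
EBioMedicine	51	26
Epigenetics Chromatin	64	25
PLoS Comput Biol	97	24
Oncogene	53	22
iScience	58	20
Sci Adv	56	20
BMC Bioinformatics	77	19
G3	74	15
Hum Mol Genet	53	15
BMC Plant Biol	52	6
Front Plant Sci	75	5
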