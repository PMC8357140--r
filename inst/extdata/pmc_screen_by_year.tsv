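year	publications_screened	excel_files_screened	excel_files_with_gene_lists	publications_with_gene_lists	suspected_publications	false_positive_files	false_positive_publications	affected_files	affected_publications
2014	19976	2948	2286	936	284	8	2	429	282
2015	21204	4318	3037	1491	490	0	0	701	490
2016	22261	4472	3331	1579	477	7	6	653	471
2017	23976	4355	3021	1412	443	5	3	648	440
2018	24986	4824	3566	1653	475	15	11	703	464
2019	26046	5481	3342	1823	594	4	3	914	591
2020	27690	6443	4496	2223	707	11	9	1038	698
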