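species	publications_with_gene_lists	affected_publications
M. musculus	1577	609
H. sapiens	7936	2419
C. elegans	124	31
D. melanogaster	607	142
S. cerevisiae	443	93
R. norvegicus	327	68
D. rerio	251	48
A. thaliana	511	76
G. gallus	1827	172
O. sativa	10	0
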