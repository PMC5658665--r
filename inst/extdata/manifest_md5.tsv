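file	md5
table1.tsv	640372397eec547650bfd85f062e4048
table2.tsv	2543e898ba4827fff2a148e389f6d128
table3a.tsv	f7d1f2c2a1e88ee854a2acd689530924
table3b.tsv	3aab83a159ded4b6db2a025875fb9c57
known_genes.txt	96b51fb923413891a3ee740990b750f7
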