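file	md5
table2_total_snps.tsv	ee1206c3017966342c3382d74441c78a
table3_homoplasmy.tsv	f61325ad1917692d9640314a361f97fe
table5_heteroplasmy.tsv	18fa34d18a4b6e5e3fd0fce7c05726f0
table7_annotations.tsv	20242baf01c0db55e5d888b243a4461c
table8_cohort.tsv	35d5c71b792900e4c5241167f6b85ab6
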