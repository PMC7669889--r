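pool	carbon	source_pool	source_carbon
ru5p	1	pentose	1
ru5p	2	pentose	2
ru5p	3	pentose	3
ru5p	4	pentose	4
ru5p	5	pentose	5
6pg	1	co2	1
6pg	2	ru5p	1
6pg	3	ru5p	2
6pg	4	ru5p	3
6pg	5	ru5p	4
6pg	6	ru5p	5
eda_pyruvate	1	6pg	1
eda_pyruvate	2	6pg	2
eda_pyruvate	3	6pg	3
gap	1	6pg	4
gap	2	6pg	5
gap	3	6pg	6
gap_pyruvate	1	gap	1
gap_pyruvate	2	gap	2
gap_pyruvate	3	gap	3
serine	1	gap	1
serine	2	gap	2
serine	3	gap	3
glycine	1	serine	1
glycine	2	serine	2
alanine	1	pyruvate_pool	1
alanine	2	pyruvate_pool	2
alanine	3	pyruvate_pool	3
valine	1	pyruvate_A	1
valine	2	pyruvate_A	2
valine	3	pyruvate_A	3
valine	4	pyruvate_B	2
valine	5	pyruvate_B	3
histidine	1	r5p	1
histidine	2	r5p	2
histidine	3	r5p	3
histidine	4	r5p	4
histidine	5	r5p	5
histidine	6	serine	3
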