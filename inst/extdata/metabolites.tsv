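# latentpath metabolite table; latentpath core fixture (rubp=FALSE, tca=FALSE)
id	name	carbons	compartment	currency	fixed_conc
13dpg_c	1,3-bisphosphoglycerate	3	c	FALSE	NA
2ddg6p_c	2-keto-3-deoxy-6-phosphogluconate	6	c	FALSE	NA
2pg_c	2-phosphoglycerate	3	c	FALSE	NA
3pg_c	3-phosphoglycerate	3	c	FALSE	NA
6pgc_c	6-phosphogluconate	6	c	FALSE	NA
6pgl_c	6-phosphogluconolactone	6	c	FALSE	NA
ac_c	acetate	2	c	FALSE	NA
ac_e	acetate	2	e	FALSE	NA
acald_c	acetaldehyde	2	c	FALSE	NA
accoa_c	acetyl-CoA	23	c	FALSE	NA
actp_c	acetyl phosphate	2	c	FALSE	NA
adp_c	ADP	10	c	TRUE	NA
amp_c	AMP	10	c	TRUE	NA
atp_c	ATP	10	c	TRUE	NA
co2_c	CO2 (dissolved)	1	c	TRUE	0.00676
co2_e	CO2 (dissolved)	1	e	TRUE	NA
coa_c	coenzyme A	21	c	FALSE	NA
dhap_c	dihydroxyacetone phosphate	3	c	FALSE	NA
e4p_c	erythrose 4-phosphate	4	c	FALSE	NA
etoh_c	ethanol	2	c	FALSE	NA
etoh_e	ethanol	2	e	FALSE	NA
f6p_c	fructose 6-phosphate	6	c	FALSE	NA
fdp_c	fructose 1,6-bisphosphate	6	c	FALSE	NA
for_c	formate	1	c	FALSE	NA
for_e	formate	1	e	FALSE	NA
g3p_c	glyceraldehyde 3-phosphate	3	c	FALSE	NA
g6p_c	glucose 6-phosphate	6	c	FALSE	NA
glc__D_c	D-glucose	6	c	FALSE	NA
glc__D_e	D-glucose	6	e	FALSE	NA
h_c	H+	0	c	TRUE	NA
h_e	H+	0	e	TRUE	NA
h2_c	hydrogen	0	c	FALSE	NA
h2_e	hydrogen	0	e	FALSE	NA
h2o_c	water	0	c	TRUE	NA
h2o_e	water	0	e	TRUE	NA
lac__D_c	D-lactate	3	c	FALSE	NA
lac__D_e	D-lactate	3	e	FALSE	NA
nad_c	NAD+	21	c	TRUE	NA
nadh_c	NADH	21	c	TRUE	NA
nadp_c	NADP+	21	c	TRUE	NA
nadph_c	NADPH	21	c	TRUE	NA
o2_c	O2	0	c	TRUE	0.001
pep_c	phosphoenolpyruvate	3	c	FALSE	NA
pi_c	phosphate	0	c	TRUE	NA
pyr_c	pyruvate	3	c	FALSE	NA
pyr_e	pyruvate	3	e	FALSE	NA
r5p_c	ribose 5-phosphate	5	c	FALSE	NA
ru5p__D_c	ribulose 5-phosphate	5	c	FALSE	NA
s7p_c	sedoheptulose 7-phosphate	7	c	FALSE	NA
xu5p__D_c	xylulose 5-phosphate	5	c	FALSE	NA
xyl__D_c	D-xylose	5	c	FALSE	NA
xyl__D_e	D-xylose	5	e	FALSE	NA
xylu__D_c	D-xylulose	5	c	FALSE	NA
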