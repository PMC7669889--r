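# latentpath reaction table; latentpath core fixture (rubp=FALSE, tca=FALSE)
id	equation	dg0_prime_kj_mol	oxygen_sensitive	lower_bound	upper_bound	notes
HEX1	atp_c + glc__D_c -> adp_c + g6p_c + h_c	-17	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PGI	g6p_c <-> f6p_c	2.17	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PFK	atp_c + f6p_c -> adp_c + fdp_c + h_c	-16.27	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
FBP	fdp_c + h2o_c -> f6p_c + pi_c	-10.95	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
FBA	fdp_c <-> dhap_c + g3p_c	20.68	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
TPI	dhap_c <-> g3p_c	5.18	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
GAPD	g3p_c + nad_c + pi_c <-> 13dpg_c + h_c + nadh_c	6.77	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PGK	13dpg_c + adp_c <-> 3pg_c + atp_c	-19.73	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PGM	3pg_c <-> 2pg_c	4.29	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ENO	2pg_c <-> h2o_c + pep_c	-3.91	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PYK	adp_c + h_c + pep_c -> atp_c + pyr_c	-25.45	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PPS	atp_c + h2o_c + pyr_c -> amp_c + 2 h_c + pep_c + pi_c	-3.54	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ZWF	g6p_c + nadp_c <-> 6pgl_c + h_c + nadph_c	-2.68	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PGL	6pgl_c + h2o_c -> 6pgc_c + h_c	-24.68	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
GND	6pgc_c + nadp_c -> co2_c + nadph_c + ru5p__D_c	10.89	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
EDD	6pgc_c -> 2ddg6p_c + h2o_c	-42.09	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
EDA	2ddg6p_c -> g3p_c + pyr_c	15.91	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
RPI	r5p_c <-> ru5p__D_c	1.94	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
RPE	ru5p__D_c <-> xu5p__D_c	-3.4	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
TKT1	r5p_c + xu5p__D_c <-> g3p_c + s7p_c	-1.5	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
TALA	g3p_c + s7p_c <-> e4p_c + f6p_c	-0.7	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
TKT2	e4p_c + xu5p__D_c <-> f6p_c + g3p_c	-10	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
XYLI1	xyl__D_c <-> xylu__D_c	4.3	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
XYLK	atp_c + xylu__D_c -> adp_c + h_c + xu5p__D_c	-17	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PDH	coa_c + nad_c + pyr_c -> accoa_c + co2_c + nadh_c	-35	FALSE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PFL	coa_c + pyr_c -> accoa_c + for_c	-19	TRUE	0	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PTAr	accoa_c + pi_c <-> actp_c + coa_c	9	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ACKr	actp_c + adp_c <-> ac_c + atp_c	-13	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ACALD	acald_c + coa_c + nad_c <-> accoa_c + h_c + nadh_c	-17	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ALCD2x	etoh_c + nad_c <-> acald_c + h_c + nadh_c	21	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
LDH_D	lac__D_c + nad_c <-> h_c + nadh_c + pyr_c	23.9	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ADK1	amp_c + atp_c <-> 2 adp_c	1.76	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
STH	nad_c + nadph_c <-> nadh_c + nadp_c	0.01	FALSE	-1000	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ATPM	atp_c + h2o_c -> adp_c + h_c + pi_c	-27.22	FALSE	6.86	1000	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
GLCt	glc__D_e <-> glc__D_c	NA	FALSE	-1000	1000	
XYLt	xyl__D_e <-> xyl__D_c	NA	FALSE	-1000	1000	
PYRt	pyr_e <-> pyr_c	NA	FALSE	-1000	1000	
LACt	lac__D_e <-> lac__D_c	NA	FALSE	-1000	1000	
ACt	ac_e <-> ac_c	NA	FALSE	-1000	1000	
ETOHt	etoh_e <-> etoh_c	NA	FALSE	-1000	1000	
FORt	for_e <-> for_c	NA	FALSE	-1000	1000	
CO2t	co2_e <-> co2_c	NA	FALSE	-1000	1000	
H2t	h2_e <-> h2_c	NA	FALSE	-1000	1000	
Ht	h_e <-> h_c	NA	FALSE	-1000	1000	
H2Ot	h2o_e <-> h2o_c	NA	FALSE	-1000	1000	
EX_glc__D_e	glc__D_e -> 	NA	FALSE	0	1000	
EX_xyl__D_e	xyl__D_e -> 	NA	FALSE	0	1000	
EX_pyr_e	pyr_e -> 	NA	FALSE	0	1000	
EX_lac__D_e	lac__D_e -> 	NA	FALSE	0	1000	
EX_ac_e	ac_e -> 	NA	FALSE	0	1000	
EX_etoh_e	etoh_e -> 	NA	FALSE	0	1000	
EX_for_e	for_e -> 	NA	FALSE	0	1000	
EX_co2_e	co2_e <-> 	NA	FALSE	-1000	1000	
EX_h2_e	h2_e -> 	NA	FALSE	0	1000	
EX_h_e	h_e <-> 	NA	FALSE	-1000	1000	
EX_h2o_e	h2o_e <-> 	NA	FALSE	-1000	1000	
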