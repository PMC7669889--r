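id	dg0_prime_kj_mol	provenance
HEX1	-17	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PGI	2.17	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PFK	-16.27	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
FBP	-10.95	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
FBA	20.68	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
TPI	5.18	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
GAPD	6.77	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PGK	-19.73	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PGM	4.29	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ENO	-3.91	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PYK	-25.45	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PPS	-3.54	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ZWF	-2.68	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PGL	-24.68	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
GND	10.89	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
EDD	-42.09	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
EDA	15.91	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
RPI	1.94	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
RPE	-3.4	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
TKT1	-1.5	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
TALA	-0.7	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
TKT2	-10	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
XYLI1	4.3	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
XYLK	-17	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PDH	-35	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PFL	-19	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
PTAr	9	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ACKr	-13	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ACALD	-17	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ALCD2x	21	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
LDH_D	23.9	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ADK1	1.76	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
STH	0.01	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
ATPM	-27.22	synthetic estimate, eQuilibrator component- contribution convention (pH 7.5, I = 0.25 M), Hess-consistent formation-energy fit
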