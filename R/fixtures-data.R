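## The authored central-metabolism fixture network.
##
## A compact E. coli-style core model: glycolysis/gluconeogenesis (with PEP
## synthetase), the Entner-Doudoroff pathway, oxidative and non-oxidative
## pentose phosphate pathway, xylose uptake, fermentation sinks (lactate,
## acetate, ethanol, formate), energy/redox bookkeeping (adenylate kinase,
## soluble transhydrogenase, ATP maintenance), and optional
## phosphoribulokinase/Rubisco and TCA blocks.
##
## dG'0 values (kJ/mol, pH 7.5, I = 0.25 M convention) are synthetic
## estimates derived from a Hess-consistent formation-energy table
## calibrated to literature values; they are vendored constants, not live
## service output.  Carbon counts include the full molecule (CoA and
## nicotinamide carbons included) so elemental carbon balances close
## exactly.

.FIXTURE_CARBONS <- c(
  glc__D = 6L, g6p = 6L, f6p = 6L, fdp = 6L, dhap = 3L, g3p = 3L,
  `13dpg` = 3L, `3pg` = 3L, `2pg` = 3L, pep = 3L, pyr = 3L,
  `6pgl` = 6L, `6pgc` = 6L, `2ddg6p` = 6L, ru5p__D = 5L, xu5p__D = 5L,
  r5p = 5L, s7p = 7L, e4p = 4L, rb15bp = 5L, xyl__D = 5L, xylu__D = 5L,
  lac__D = 3L, ac = 2L, actp = 2L, etoh = 2L, acald = 2L,
  accoa = 23L, coa = 21L, `for` = 1L, h2 = 0L, co2 = 1L,
  atp = 10L, adp = 10L, amp = 10L, pi = 0L,
  nad = 21L, nadh = 21L, nadp = 21L, nadph = 21L,
  h = 0L, h2o = 0L, o2 = 0L,
  oaa = 4L, cit = 6L, icit = 6L, akg = 5L, succoa = 25L, succ = 4L,
  mal__L = 4L, fum = 4L)

.FIXTURE_NAMES <- c(
  glc__D = "D-glucose", g6p = "glucose 6-phosphate",
  f6p = "fructose 6-phosphate", fdp = "fructose 1,6-bisphosphate",
  dhap = "dihydroxyacetone phosphate", g3p = "glyceraldehyde 3-phosphate",
  `13dpg` = "1,3-bisphosphoglycerate", `3pg` = "3-phosphoglycerate",
  `2pg` = "2-phosphoglycerate", pep = "phosphoenolpyruvate",
  pyr = "pyruvate", `6pgl` = "6-phosphogluconolactone",
  `6pgc` = "6-phosphogluconate",
  `2ddg6p` = "2-keto-3-deoxy-6-phosphogluconate",
  ru5p__D = "ribulose 5-phosphate", xu5p__D = "xylulose 5-phosphate",
  r5p = "ribose 5-phosphate", s7p = "sedoheptulose 7-phosphate",
  e4p = "erythrose 4-phosphate", rb15bp = "ribulose 1,5-bisphosphate",
  xyl__D = "D-xylose", xylu__D = "D-xylulose", lac__D = "D-lactate",
  ac = "acetate", actp = "acetyl phosphate", etoh = "ethanol",
  acald = "acetaldehyde", accoa = "acetyl-CoA", coa = "coenzyme A",
  `for` = "formate", h2 = "hydrogen", co2 = "CO2 (dissolved)",
  atp = "ATP", adp = "ADP", amp = "AMP", pi = "phosphate",
  nad = "NAD+", nadh = "NADH", nadp = "NADP+", nadph = "NADPH",
  h = "H+", h2o = "water", o2 = "O2",
  oaa = "oxaloacetate", cit = "citrate", icit = "isocitrate",
  akg = "2-oxoglutarate", succoa = "succinyl-CoA", succ = "succinate",
  mal__L = "L-malate", fum = "fumarate")

## id | equation | dg0 | lb | ub | o2sens | group
## group: core / rubp / tca / transport / exchange
.FIXTURE_REACTIONS <- list(
  list("HEX1",  "glc__D_c + atp_c -> g6p_c + adp_c + h_c",            -17.00,    0, 1000, FALSE, "core"),
  list("PGI",   "g6p_c <-> f6p_c",                                      2.17, -1000, 1000, FALSE, "core"),
  list("PFK",   "f6p_c + atp_c -> fdp_c + adp_c + h_c",               -16.27,    0, 1000, FALSE, "core"),
  list("FBP",   "fdp_c + h2o_c -> f6p_c + pi_c",                      -10.95,    0, 1000, FALSE, "core"),
  list("FBA",   "fdp_c <-> dhap_c + g3p_c",                            20.68, -1000, 1000, FALSE, "core"),
  list("TPI",   "dhap_c <-> g3p_c",                                     5.18, -1000, 1000, FALSE, "core"),
  list("GAPD",  "g3p_c + nad_c + pi_c <-> 13dpg_c + nadh_c + h_c",      6.77, -1000, 1000, FALSE, "core"),
  list("PGK",   "13dpg_c + adp_c <-> 3pg_c + atp_c",                  -19.73, -1000, 1000, FALSE, "core"),
  list("PGM",   "3pg_c <-> 2pg_c",                                      4.29, -1000, 1000, FALSE, "core"),
  list("ENO",   "2pg_c <-> pep_c + h2o_c",                             -3.91, -1000, 1000, FALSE, "core"),
  list("PYK",   "pep_c + adp_c + h_c -> pyr_c + atp_c",               -25.45,    0, 1000, FALSE, "core"),
  list("PPS",   "pyr_c + atp_c + h2o_c -> pep_c + amp_c + pi_c + 2 h_c", -3.54, 0, 1000, FALSE, "core"),
  list("ZWF",   "g6p_c + nadp_c <-> 6pgl_c + nadph_c + h_c",           -2.68, -1000, 1000, FALSE, "core"),
  list("PGL",   "6pgl_c + h2o_c -> 6pgc_c + h_c",                     -24.68,    0, 1000, FALSE, "core"),
  list("GND",   "6pgc_c + nadp_c -> ru5p__D_c + co2_c + nadph_c",      10.89,    0, 1000, FALSE, "core"),
  list("EDD",   "6pgc_c -> 2ddg6p_c + h2o_c",                         -42.09,    0, 1000, FALSE, "core"),
  list("EDA",   "2ddg6p_c -> pyr_c + g3p_c",                           15.91,    0, 1000, FALSE, "core"),
  list("RPI",   "r5p_c <-> ru5p__D_c",                                  1.94, -1000, 1000, FALSE, "core"),
  list("RPE",   "ru5p__D_c <-> xu5p__D_c",                             -3.40, -1000, 1000, FALSE, "core"),
  list("TKT1",  "xu5p__D_c + r5p_c <-> s7p_c + g3p_c",                 -1.50, -1000, 1000, FALSE, "core"),
  list("TALA",  "s7p_c + g3p_c <-> e4p_c + f6p_c",                     -0.70, -1000, 1000, FALSE, "core"),
  list("TKT2",  "xu5p__D_c + e4p_c <-> f6p_c + g3p_c",                -10.00, -1000, 1000, FALSE, "core"),
  list("XYLI1", "xyl__D_c <-> xylu__D_c",                               4.30, -1000, 1000, FALSE, "core"),
  list("XYLK",  "xylu__D_c + atp_c -> xu5p__D_c + adp_c + h_c",       -17.00,    0, 1000, FALSE, "core"),
  list("PDH",   "pyr_c + coa_c + nad_c -> accoa_c + co2_c + nadh_c",  -35.00,    0, 1000, FALSE, "core"),
  list("PFL",   "pyr_c + coa_c -> accoa_c + for_c",                   -19.00,    0, 1000, TRUE,  "core"),
  list("PTAr",  "accoa_c + pi_c <-> actp_c + coa_c",                    9.00, -1000, 1000, FALSE, "core"),
  list("ACKr",  "actp_c + adp_c <-> ac_c + atp_c",                    -13.00, -1000, 1000, FALSE, "core"),
  list("ACALD", "acald_c + coa_c + nad_c <-> accoa_c + nadh_c + h_c", -17.00, -1000, 1000, FALSE, "core"),
  list("ALCD2x","etoh_c + nad_c <-> acald_c + nadh_c + h_c",           21.00, -1000, 1000, FALSE, "core"),
  list("LDH_D", "lac__D_c + nad_c <-> pyr_c + nadh_c + h_c",           23.90, -1000, 1000, FALSE, "core"),
  list("ADK1",  "amp_c + atp_c <-> 2 adp_c",                            1.76, -1000, 1000, FALSE, "core"),
  list("STH",   "nadph_c + nad_c <-> nadp_c + nadh_c",                  0.01, -1000, 1000, FALSE, "core"),
  list("ATPM",  "atp_c + h2o_c -> adp_c + pi_c + h_c",                -27.22, 6.86, 1000, FALSE, "core"),
  ## optional phosphoribulokinase / Rubisco
  list("PRK",   "ru5p__D_c + atp_c -> rb15bp_c + adp_c + h_c",        -17.59,    0, 1000, FALSE, "rubp"),
  list("RBPC",  "rb15bp_c + co2_c + h2o_c -> 2 3pg_c + 2 h_c",        -34.59,    0, 1000, FALSE, "rubp"),
  ## optional TCA / anaplerosis block
  list("PPC",   "pep_c + co2_c + h2o_c -> oaa_c + pi_c + h_c",        -30.00,    0, 1000, FALSE, "tca"),
  list("CS",    "accoa_c + oaa_c + h2o_c -> cit_c + coa_c + h_c",     -35.00,    0, 1000, FALSE, "tca"),
  list("ACONT", "cit_c <-> icit_c",                                     8.50, -1000, 1000, FALSE, "tca"),
  list("ICDHyr","icit_c + nadp_c <-> akg_c + co2_c + nadph_c",          5.00, -1000, 1000, FALSE, "tca"),
  list("AKGDH", "akg_c + coa_c + nad_c -> succoa_c + co2_c + nadh_c", -28.00,    0, 1000, FALSE, "tca"),
  list("SUCOAS","succ_c + coa_c + atp_c <-> succoa_c + adp_c + pi_c",   1.50, -1000, 1000, FALSE, "tca"),
  list("MDH",   "mal__L_c + nad_c <-> oaa_c + nadh_c + h_c",           26.00, -1000, 1000, FALSE, "tca"),
  list("FUM",   "fum_c + h2o_c <-> mal__L_c",                          -3.40, -1000, 1000, FALSE, "tca"),
  ## transport (simple diffusion; proton symport deliberately not modelled)
  list("GLCt",  "glc__D_e <-> glc__D_c",                            NA, -1000, 1000, FALSE, "transport"),
  list("XYLt",  "xyl__D_e <-> xyl__D_c",                            NA, -1000, 1000, FALSE, "transport"),
  list("PYRt",  "pyr_e <-> pyr_c",                                  NA, -1000, 1000, FALSE, "transport"),
  list("LACt",  "lac__D_e <-> lac__D_c",                            NA, -1000, 1000, FALSE, "transport"),
  list("ACt",   "ac_e <-> ac_c",                                    NA, -1000, 1000, FALSE, "transport"),
  list("ETOHt", "etoh_e <-> etoh_c",                                NA, -1000, 1000, FALSE, "transport"),
  list("FORt",  "for_e <-> for_c",                                  NA, -1000, 1000, FALSE, "transport"),
  list("CO2t",  "co2_e <-> co2_c",                                  NA, -1000, 1000, FALSE, "transport"),
  list("H2t",   "h2_e <-> h2_c",                                    NA, -1000, 1000, FALSE, "transport"),
  list("Ht",    "h_e <-> h_c",                                      NA, -1000, 1000, FALSE, "transport"),
  list("H2Ot",  "h2o_e <-> h2o_c",                                  NA, -1000, 1000, FALSE, "transport"),
  list("SUCCt", "succ_e <-> succ_c",                                NA, -1000, 1000, FALSE, "tca_transport"),
  ## exchanges (negative flux = uptake; uptakes closed by default except
  ## the freely available inorganics)
  list("EX_glc__D_e", "glc__D_e ->",                                NA,     0, 1000, FALSE, "exchange"),
  list("EX_xyl__D_e", "xyl__D_e ->",                                NA,     0, 1000, FALSE, "exchange"),
  list("EX_pyr_e",    "pyr_e ->",                                   NA,     0, 1000, FALSE, "exchange"),
  list("EX_lac__D_e", "lac__D_e ->",                                NA,     0, 1000, FALSE, "exchange"),
  list("EX_ac_e",     "ac_e ->",                                    NA,     0, 1000, FALSE, "exchange"),
  list("EX_etoh_e",   "etoh_e ->",                                  NA,     0, 1000, FALSE, "exchange"),
  list("EX_for_e",    "for_e ->",                                   NA,     0, 1000, FALSE, "exchange"),
  list("EX_co2_e",    "co2_e <->",                                  NA, -1000, 1000, FALSE, "exchange"),
  list("EX_h2_e",     "h2_e ->",                                    NA,     0, 1000, FALSE, "exchange"),
  list("EX_h_e",      "h_e <->",                                    NA, -1000, 1000, FALSE, "exchange"),
  list("EX_h2o_e",    "h2o_e <->",                                  NA, -1000, 1000, FALSE, "exchange"),
  list("EX_succ_e",   "succ_e ->",                                  NA,     0, 1000, FALSE, "tca_exchange")
)

.DG0_PROVENANCE <- paste("synthetic estimate, eQuilibrator component-",
                         "contribution convention (pH 7.5, I = 0.25 M),",
                         "Hess-consistent formation-energy fit")
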