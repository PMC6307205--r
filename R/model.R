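# The FGF/VEGF -> MAPK signaling model.
#
# The network realizes, with mass-action kinetics throughout:
#   * FGF binding surface HSGAGs and (competitively, non-signaling) FGFR1;
#     the signaling ternary complex forms only by FGFR1 binding FGF:HSGAG.
#   * Ternary-complex dimerization, phosphorylation of the dimer, recruitment
#     and phosphorylation of FRS2, and ppERK-driven FRS2 ubiquitination
#     (negative feedback).
#   * One-step VEGFR2 autophosphorylation on VEGF binding, Ras activation via
#     Shc-independent (Grb2:Sos on pR2) and Shc-dependent routes, Raf
#     activation by Ras-GTP.
#   * Distributive two-site phosphorylation of MEK by pFRS2 and aRaf, and of
#     ERK by ppMEK; dephosphorylation by the phosphatases Ptase1 (pFRS2),
#     Ptase2 (pMEK/ppMEK, association rate k_dpMEK_p, catalytic rate ked2) and
#     Ptase3 (pERK/ppERK).
#   * Internalization/recycling/degradation of free and bound FGFR1 (one
#     shared rate set for all bound forms), of HSGAGs (constitutive turnover,
#     sharing the free-FGFR1 rates), and of free and bound VEGFR2 (six rates).
# Degradation moves material into explicit degraded-pool species so every
# protein moiety is conserved.

PROTEINS <- c("FGF", "HSGAG", "FGFR1", "VEGF", "VEGFR2", "FRS2", "Shc",
              "Grb2", "Sos", "Ras", "Raf", "MEK", "ERK",
              "Ptase1", "Ptase2", "Ptase3", "HEP")

#' Default initial amounts of the signaling model
#'
#' Receptor and co-receptor densities follow reported surface levels
#' (FGFR1 20,000, VEGFR2 1,000, HSGAGs 1e5 molecules/cell); cytosolic pools
#' are the reconstruction's baseline values. Ligands start at 0 and are set by
#' the stimulation protocol.
#'
#' @return Named numeric vector (molecules/cell; nM for ligands).
#' @export
default_initial_amounts <- function() {
  c(FGF = 0, VEGF = 0,
    HSGAG = 1e5, FGFR1 = 2e4, VEGFR2 = 1e3,
    FRS2 = 1.2e4, Ptase1 = 6e3,
    Shc = 1e5, Grb2 = 1e5, Sos = 4e4,
    Ras = 8e4, Raf = 1.2e5,
    MEK = 7e5, ERK = 2.1e6,
    Ptase2 = 4.491e4, Ptase3 = 2.453e4)
}

#' Baseline rate constants of the signaling model
#'
#' Units: first-order rates 1/min; bimolecular rates 1/(molecules/cell x min)
#' except the ligand-facing on-rates (`kon_FGF_HSGAG`, `kon_FGF_FGFR1`,
#' `k_pR2`, `kon_FGF_HEP`, `kon_TCh`), which are 1/(nM x min) because the
#' ligand factor of those fluxes is a clamped concentration.
#'
#' @return Named numeric vector of the 75 main-model rate constants.
#' @export
default_parameters <- function() {
  c(
    ## FGF capture and ternary-complex assembly
    kon_FGF_HSGAG = 0.3,    koff_FGF_HSGAG = 0.05,
    kon_FGF_FGFR1 = 0.5,    koff_FGF_FGFR1 = 0.05,
    kon_TC = 1e-4,          koff_TC = 0.1,
    kon_dim = 1e-3,         koff_dim = 0.05,
    k_phDC = 4,             k_dphDC = 0.2,
    ## FRS2 recruitment, phosphorylation, dephosphorylation, feedback
    kon_pDC_FRS2 = 1.4e-3,  koff_pDC_FRS2 = 0.5,
    k_phFRS2 = 20,          k_rel_pFRS2 = 10,
    kon_Ptase1_pFRS2 = 1e-4, koff_Ptase1_pFRS2 = 0.5, ked1 = 5,
    kon_ppERK_FRS2 = 1.4e-5, koff_ppERK_FRS2 = 0.5,
    k_ub = 2,               k_deub = 0.002,
    ## VEGFR2 autophosphorylation and Ras activation
    k_pR2 = 0.3,            k_dpR2 = 1.5,
    kon_GS = 1e-6,          koff_GS = 0.1,
    kon_pR2_GS = 5e-5,      koff_pR2_GS = 0.3,
    kon_pR2_Shc = 1e-6,     koff_pR2_Shc = 0.1,
    k_phShc = 2,
    kon_pShc_GS = 2e-5,     koff_pShc_GS = 0.3,
    kcat_GEF = 1.657e-3,    k_hyd = 1.5,  k_dphShc = 0.5,
    ## Raf activation
    kon_RasGTP_Raf = 8e-6,  koff_RasGTP_Raf = 0.1,
    kcat_Raf = 5,           k_dRaf = 1.113,
    ## MEK phosphorylation (distributive, two kinases)
    kon_pFRS2_MEK = 3.234e-4,  koff_pFRS2_MEK = 0.3,  kcat_pFRS2_MEK = 522.9,
    kon_pFRS2_pMEK = 3.234e-4, koff_pFRS2_pMEK = 0.3, kcat_pFRS2_pMEK = 522.9,
    kon_aRaf_MEK = 2.541e-4,   koff_aRaf_MEK = 0.3,   kcat_aRaf_MEK = 18,
    kon_aRaf_pMEK = 2.541e-4,  koff_aRaf_pMEK = 0.3,  kcat_aRaf_pMEK = 18,
    k_dpMEK_p = 1.701e-3,      koff_Ptase2_MEK = 1.8, ked2 = 19.2,
    ## ERK phosphorylation and dephosphorylation
    kon_ppMEK_ERK = 2.102e-6,  koff_ppMEK_ERK = 0.3,  kcat_ppMEK_ERK = 36,
    kon_ppMEK_pERK = 2.102e-6, koff_ppMEK_pERK = 0.3, kcat_ppMEK_pERK = 36,
    kon_Ptase3_ERK = 7.566e-5, koff_Ptase3_ERK = 1.8, ked3 = 2.873,
    ## Trafficking: FGFR1 (free / all bound forms) and VEGFR2 (free / bound)
    k_intf_R1 = 0.005, k_recf_R1 = 0.01, k_degf_R1 = 0.002,
    k_intb_R1 = 0.08,  k_recb_R1 = 0.01, k_degb_R1 = 0.01,
    k_intf = 0.2,      k_recf = 0.1,     k_degf = 0.15,
    k_intb = 0.3,      k_recb = 0.1,     k_degb = 0.16)
}

#' Rate constants added by the heparin extension
#' @return Named numeric vector of the 3 heparin parameters: solution
#'   FGF-heparin binding (1/(nM x min) and 1/min) and the on-rate of the
#'   soluble FGF:heparin complex for surface FGFR1 (1/(nM x min)).
#' @export
default_heparin_parameters <- function() {
  c(kon_FGF_HEP = 0.015, koff_FGF_HEP = 1.5, kon_TCh = 0.002)
}

main_species_list <- function(init) {
  cmp <- function(...) c(...)
  surf <- function(name, comp, init_amt = 0) species(name, "surface", init_amt, FALSE, comp)
  cyt <- function(name, comp, init_amt = 0) species(name, "internal", init_amt, FALSE, comp)
  deg <- function(name, comp) species(name, "degraded_pool", 0, FALSE, comp)
  i_of <- function(name, comp) species(name, "internal", 0, FALSE, comp)

  tc <- cmp(FGF = 1, HSGAG = 1, FGFR1 = 1)
  dc <- cmp(FGF = 2, HSGAG = 2, FGFR1 = 2)
  dcf <- cmp(FGF = 2, HSGAG = 2, FGFR1 = 2, FRS2 = 1)
  pr2 <- cmp(VEGF = 1, VEGFR2 = 1)

  list(
    species("FGF", "extracellular", init[["FGF"]], TRUE, cmp(FGF = 1)),
    species("VEGF", "extracellular", init[["VEGF"]], TRUE, cmp(VEGF = 1)),
    surf("HSGAG", cmp(HSGAG = 1), init[["HSGAG"]]),
    surf("FGFR1", cmp(FGFR1 = 1), init[["FGFR1"]]),
    surf("FGF_HSGAG", cmp(FGF = 1, HSGAG = 1)),
    surf("FGF_FGFR1", cmp(FGF = 1, FGFR1 = 1)),
    surf("TC", tc),
    surf("DC", dc),
    surf("pDC", dc),
    cyt("FRS2", cmp(FRS2 = 1), init[["FRS2"]]),
    surf("pDC_FRS2", dcf),
    surf("pDC_pFRS2", dcf),
    cyt("pFRS2", cmp(FRS2 = 1)),
    cyt("FRS2u", cmp(FRS2 = 1)),
    cyt("ppERK_FRS2", cmp(ERK = 1, FRS2 = 1)),
    cyt("ppERK_pFRS2", cmp(ERK = 1, FRS2 = 1)),
    cyt("Ptase1", cmp(Ptase1 = 1), init[["Ptase1"]]),
    cyt("Ptase1_pFRS2", cmp(Ptase1 = 1, FRS2 = 1)),
    surf("VEGFR2", cmp(VEGFR2 = 1), init[["VEGFR2"]]),
    surf("pR2", pr2),
    cyt("Grb2", cmp(Grb2 = 1), init[["Grb2"]]),
    cyt("Sos", cmp(Sos = 1), init[["Sos"]]),
    cyt("Grb2_Sos", cmp(Grb2 = 1, Sos = 1)),
    cyt("Shc", cmp(Shc = 1), init[["Shc"]]),
    cyt("pShc", cmp(Shc = 1)),
    surf("pR2_Grb2_Sos", c(pr2, cmp(Grb2 = 1, Sos = 1))),
    surf("pR2_Shc", c(pr2, cmp(Shc = 1))),
    surf("pR2_Shc_Grb2_Sos", c(pr2, cmp(Shc = 1, Grb2 = 1, Sos = 1))),
    cyt("pShc_Grb2_Sos", cmp(Shc = 1, Grb2 = 1, Sos = 1)),
    cyt("Ras", cmp(Ras = 1), init[["Ras"]]),
    cyt("RasGTP", cmp(Ras = 1)),
    cyt("Raf", cmp(Raf = 1), init[["Raf"]]),
    cyt("RasGTP_Raf", cmp(Ras = 1, Raf = 1)),
    cyt("aRaf", cmp(Raf = 1)),
    cyt("MEK", cmp(MEK = 1), init[["MEK"]]),
    cyt("pMEK", cmp(MEK = 1)),
    cyt("ppMEK", cmp(MEK = 1)),
    cyt("ERK", cmp(ERK = 1), init[["ERK"]]),
    cyt("pERK", cmp(ERK = 1)),
    cyt("ppERK", cmp(ERK = 1)),
    cyt("Ptase2", cmp(Ptase2 = 1), init[["Ptase2"]]),
    cyt("Ptase3", cmp(Ptase3 = 1), init[["Ptase3"]]),
    cyt("pFRS2_MEK", cmp(FRS2 = 1, MEK = 1)),
    cyt("pFRS2_pMEK", cmp(FRS2 = 1, MEK = 1)),
    cyt("aRaf_MEK", cmp(Raf = 1, MEK = 1)),
    cyt("aRaf_pMEK", cmp(Raf = 1, MEK = 1)),
    cyt("ppMEK_ERK", cmp(MEK = 1, ERK = 1)),
    cyt("ppMEK_pERK", cmp(MEK = 1, ERK = 1)),
    cyt("Ptase2_pMEK", cmp(Ptase2 = 1, MEK = 1)),
    cyt("Ptase2_ppMEK", cmp(Ptase2 = 1, MEK = 1)),
    cyt("Ptase3_pERK", cmp(Ptase3 = 1, ERK = 1)),
    cyt("Ptase3_ppERK", cmp(Ptase3 = 1, ERK = 1)),
    i_of("FGFR1_i", cmp(FGFR1 = 1)),
    i_of("FGF_FGFR1_i", cmp(FGF = 1, FGFR1 = 1)),
    i_of("TC_i", tc),
    i_of("DC_i", dc),
    i_of("pDC_i", dc),
    i_of("pDC_FRS2_i", dcf),
    i_of("pDC_pFRS2_i", dcf),
    deg("FGFR1_deg", cmp(FGFR1 = 1)),
    deg("FGF_FGFR1_deg", cmp(FGF = 1, FGFR1 = 1)),
    deg("TC_deg", tc),
    deg("DC_deg", dc),
    deg("pDC_deg", dc),
    deg("pDC_FRS2_deg", dcf),
    deg("pDC_pFRS2_deg", dcf),
    i_of("HSGAG_i", cmp(HSGAG = 1)),
    deg("HSGAG_deg", cmp(HSGAG = 1)),
    i_of("VEGFR2_i", cmp(VEGFR2 = 1)),
    deg("VEGFR2_deg", cmp(VEGFR2 = 1)),
    i_of("pR2_i", pr2),
    deg("pR2_deg", pr2))
}

# Internalization + recycling are one reversible reaction; degradation is a
# second, irreversible one. `n0` is the label counter start.
traffic_reactions <- function(form, n0, kint, krec, kdeg) {
  list(
    reaction(sprintf("R%02d", n0), setNames(1, form),
             setNames(1, paste0(form, "_i")), kint, krec),
    reaction(sprintf("R%02d", n0 + 1L), setNames(1, paste0(form, "_i")),
             setNames(1, paste0(form, "_deg")), kdeg))
}

main_reaction_list <- function() {
  rx <- function(label, reactants, products, kf, kr = NA) {
    reaction(label, reactants, products, kf, kr)
  }
  r <- list(
    rx("R01", c(FGF = 1, HSGAG = 1), c(FGF_HSGAG = 1),
       "kon_FGF_HSGAG", "koff_FGF_HSGAG"),
    rx("R02", c(FGF = 1, FGFR1 = 1), c(FGF_FGFR1 = 1),
       "kon_FGF_FGFR1", "koff_FGF_FGFR1"),
    rx("R03", c(FGF_HSGAG = 1, FGFR1 = 1), c(TC = 1), "kon_TC", "koff_TC"),
    rx("R04", c(TC = 2), c(DC = 1), "kon_dim", "koff_dim"),
    rx("R05", c(DC = 1), c(pDC = 1), "k_phDC", "k_dphDC"),
    rx("R06", c(pDC = 1, FRS2 = 1), c(pDC_FRS2 = 1),
       "kon_pDC_FRS2", "koff_pDC_FRS2"),
    rx("R07", c(pDC_FRS2 = 1), c(pDC_pFRS2 = 1), "k_phFRS2"),
    rx("R08", c(pDC_pFRS2 = 1), c(pDC = 1, pFRS2 = 1),
       "k_rel_pFRS2", "kon_pDC_FRS2"),
    rx("R09", c(pFRS2 = 1, Ptase1 = 1), c(Ptase1_pFRS2 = 1),
       "kon_Ptase1_pFRS2", "koff_Ptase1_pFRS2"),
    rx("R10", c(Ptase1_pFRS2 = 1), c(Ptase1 = 1, FRS2 = 1), "ked1"),
    rx("R11", c(ppERK = 1, FRS2 = 1), c(ppERK_FRS2 = 1),
       "kon_ppERK_FRS2", "koff_ppERK_FRS2"),
    rx("R12", c(ppERK_FRS2 = 1), c(ppERK = 1, FRS2u = 1), "k_ub"),
    rx("R13", c(ppERK = 1, pFRS2 = 1), c(ppERK_pFRS2 = 1),
       "kon_ppERK_FRS2", "koff_ppERK_FRS2"),
    rx("R14", c(ppERK_pFRS2 = 1), c(ppERK = 1, FRS2u = 1), "k_ub"),
    rx("R15", c(FRS2u = 1), c(FRS2 = 1), "k_deub"),
    rx("R16", c(VEGF = 1, VEGFR2 = 1), c(pR2 = 1), "k_pR2", "k_dpR2"),
    rx("R17", c(Grb2 = 1, Sos = 1), c(Grb2_Sos = 1), "kon_GS", "koff_GS"),
    rx("R18", c(pR2 = 1, Grb2_Sos = 1), c(pR2_Grb2_Sos = 1),
       "kon_pR2_GS", "koff_pR2_GS"),
    rx("R19", c(pR2 = 1, Shc = 1), c(pR2_Shc = 1),
       "kon_pR2_Shc", "koff_pR2_Shc"),
    rx("R20", c(pR2_Shc = 1), c(pR2 = 1, pShc = 1), "k_phShc"),
    rx("R21", c(pShc = 1, Grb2_Sos = 1), c(pShc_Grb2_Sos = 1),
       "kon_pShc_GS", "koff_pShc_GS"),
    rx("R22", c(pR2_Shc = 1, Grb2_Sos = 1), c(pR2_Shc_Grb2_Sos = 1),
       "kon_pShc_GS", "koff_pShc_GS"),
    rx("R23", c(pR2_Grb2_Sos = 1, Ras = 1), c(pR2_Grb2_Sos = 1, RasGTP = 1),
       "kcat_GEF"),
    rx("R24", c(pShc_Grb2_Sos = 1, Ras = 1), c(pShc_Grb2_Sos = 1, RasGTP = 1),
       "kcat_GEF"),
    rx("R25", c(pR2_Shc_Grb2_Sos = 1, Ras = 1),
       c(pR2_Shc_Grb2_Sos = 1, RasGTP = 1), "kcat_GEF"),
    rx("R26", c(RasGTP = 1), c(Ras = 1), "k_hyd"),
    rx("R27", c(pShc = 1), c(Shc = 1), "k_dphShc"),
    rx("R28", c(RasGTP = 1, Raf = 1), c(RasGTP_Raf = 1),
       "kon_RasGTP_Raf", "koff_RasGTP_Raf"),
    rx("R29", c(RasGTP_Raf = 1), c(RasGTP = 1, aRaf = 1), "kcat_Raf"),
    rx("R30", c(aRaf = 1), c(Raf = 1), "k_dRaf"),
    rx("R31", c(pFRS2 = 1, MEK = 1), c(pFRS2_MEK = 1),
       "kon_pFRS2_MEK", "koff_pFRS2_MEK"),
    rx("R32", c(pFRS2_MEK = 1), c(pFRS2 = 1, pMEK = 1), "kcat_pFRS2_MEK"),
    rx("R33", c(pFRS2 = 1, pMEK = 1), c(pFRS2_pMEK = 1),
       "kon_pFRS2_pMEK", "koff_pFRS2_pMEK"),
    rx("R34", c(pFRS2_pMEK = 1), c(pFRS2 = 1, ppMEK = 1), "kcat_pFRS2_pMEK"),
    rx("R35", c(aRaf = 1, MEK = 1), c(aRaf_MEK = 1),
       "kon_aRaf_MEK", "koff_aRaf_MEK"),
    rx("R36", c(aRaf_MEK = 1), c(aRaf = 1, pMEK = 1), "kcat_aRaf_MEK"),
    rx("R37", c(aRaf = 1, pMEK = 1), c(aRaf_pMEK = 1),
       "kon_aRaf_pMEK", "koff_aRaf_pMEK"),
    rx("R38", c(aRaf_pMEK = 1), c(aRaf = 1, ppMEK = 1), "kcat_aRaf_pMEK"),
    rx("R39", c(Ptase2 = 1, ppMEK = 1), c(Ptase2_ppMEK = 1),
       "k_dpMEK_p", "koff_Ptase2_MEK"),
    rx("R40", c(Ptase2_ppMEK = 1), c(Ptase2 = 1, pMEK = 1), "ked2"),
    rx("R41", c(Ptase2 = 1, pMEK = 1), c(Ptase2_pMEK = 1),
       "k_dpMEK_p", "koff_Ptase2_MEK"),
    rx("R42", c(Ptase2_pMEK = 1), c(Ptase2 = 1, MEK = 1), "ked2"),
    rx("R43", c(ppMEK = 1, ERK = 1), c(ppMEK_ERK = 1),
       "kon_ppMEK_ERK", "koff_ppMEK_ERK"),
    rx("R44", c(ppMEK_ERK = 1), c(ppMEK = 1, pERK = 1), "kcat_ppMEK_ERK"),
    rx("R45", c(ppMEK = 1, pERK = 1), c(ppMEK_pERK = 1),
       "kon_ppMEK_pERK", "koff_ppMEK_pERK"),
    rx("R46", c(ppMEK_pERK = 1), c(ppMEK = 1, ppERK = 1), "kcat_ppMEK_pERK"),
    rx("R47", c(Ptase3 = 1, ppERK = 1), c(Ptase3_ppERK = 1),
       "kon_Ptase3_ERK", "koff_Ptase3_ERK"),
    rx("R48", c(Ptase3_ppERK = 1), c(Ptase3 = 1, pERK = 1), "ked3"),
    rx("R49", c(Ptase3 = 1, pERK = 1), c(Ptase3_pERK = 1),
       "kon_Ptase3_ERK", "koff_Ptase3_ERK"),
    rx("R50", c(Ptase3_pERK = 1), c(Ptase3 = 1, ERK = 1), "ked3"))
  n <- 51L
  for (spec in list(
    list("FGFR1", "k_intf_R1", "k_recf_R1", "k_degf_R1"),
    list("FGF_FGFR1", "k_intb_R1", "k_recb_R1", "k_degb_R1"),
    list("TC", "k_intb_R1", "k_recb_R1", "k_degb_R1"),
    list("DC", "k_intb_R1", "k_recb_R1", "k_degb_R1"),
    list("pDC", "k_intb_R1", "k_recb_R1", "k_degb_R1"),
    list("pDC_FRS2", "k_intb_R1", "k_recb_R1", "k_degb_R1"),
    list("pDC_pFRS2", "k_intb_R1", "k_recb_R1", "k_degb_R1"),
    list("HSGAG", "k_intf_R1", "k_recf_R1", "k_degf_R1"),
    list("VEGFR2", "k_intf", "k_recf", "k_degf"),
    list("pR2", "k_intb", "k_recb", "k_degb"))) {
    r <- c(r, traffic_reactions(spec[[1]], n, spec[[2]], spec[[3]], spec[[4]]))
    n <- n + 2L
  }
  r
}

readout_defs_main <- function() {
  list(
    pERK_total = c("pERK", "ppERK", "ppMEK_pERK", "Ptase3_pERK",
                   "Ptase3_ppERK", "ppERK_FRS2", "ppERK_pFRS2"),
    pR2_total = c("pR2", "pR2_Grb2_Sos", "pR2_Shc", "pR2_Shc_Grb2_Sos",
                  "pR2_i"),
    pFRS2 = c("pFRS2", "pDC_pFRS2", "pDC_pFRS2_i", "pFRS2_MEK", "pFRS2_pMEK",
              "Ptase1_pFRS2", "ppERK_pFRS2"),
    ppMEK = c("ppMEK", "ppMEK_ERK", "ppMEK_pERK", "Ptase2_ppMEK"),
    aRaf = c("aRaf", "aRaf_MEK", "aRaf_pMEK"),
    RasGTP = c("RasGTP", "RasGTP_Raf"),
    FRS2_free = "FRS2")
}

arm_tags_main <- function(labels) {
  tag <- rep("trafficking", length(labels))
  idx <- as.integer(sub("^R", "", labels))
  tag[idx <= 15] <- "FGF_arm"
  tag[idx >= 16 & idx <= 30] <- "VEGF_arm"
  tag[idx >= 31 & idx <= 50] <- "shared_MAPK"
  setNames(tag, labels)
}

#' Names of the free (fitted) quantities
#'
#' The 39 calibrated quantities: the 24 rate constants of the shared MAPK
#' cascade (MEK/ERK (de)phosphorylation), the 4 Raf activation/deactivation
#' constants, the 6 VEGFR2 trafficking rates, and the 5 influential initial
#' amounts (FRS2, Ptase2, Ras, MEK, Raf).
#'
#' @return Character vector of length 39.
#' @export
free_parameter_names <- function() {
  c("kon_pFRS2_MEK", "koff_pFRS2_MEK", "kcat_pFRS2_MEK",
    "kon_pFRS2_pMEK", "koff_pFRS2_pMEK", "kcat_pFRS2_pMEK",
    "kon_aRaf_MEK", "koff_aRaf_MEK", "kcat_aRaf_MEK",
    "kon_aRaf_pMEK", "koff_aRaf_pMEK", "kcat_aRaf_pMEK",
    "k_dpMEK_p", "koff_Ptase2_MEK", "ked2",
    "kon_ppMEK_ERK", "koff_ppMEK_ERK", "kcat_ppMEK_ERK",
    "kon_ppMEK_pERK", "koff_ppMEK_pERK", "kcat_ppMEK_pERK",
    "kon_Ptase3_ERK", "koff_Ptase3_ERK", "ked3",
    "kon_RasGTP_Raf", "koff_RasGTP_Raf", "kcat_Raf", "k_dRaf",
    "k_intf", "k_recf", "k_degf", "k_intb", "k_recb", "k_degb",
    "FRS2", "Ptase2", "Ras", "MEK", "Raf")
}

#' Build the main FGF/VEGF signaling model
#'
#' Assembles the reconstructed reaction network (70 reactions, 72 species, 75
#' rate constants), its arm tags, readout definitions and the designated free
#' quantities.
#'
#' @param parameters Optional overrides of [default_parameters()].
#' @param initial_amounts Optional overrides of [default_initial_amounts()].
#' @return Object of class `signaling_model` with elements `network`,
#'   `arm_tags`, `readout_defs`, `free_names`, `kind`.
#' @export
build_main_network <- function(parameters = NULL, initial_amounts = NULL) {
  init <- default_initial_amounts()
  if (!is.null(initial_amounts)) init[names(initial_amounts)] <- initial_amounts
  pars <- default_parameters()
  if (!is.null(parameters)) pars[names(parameters)] <- parameters
  net <- reaction_network(main_species_list(init), main_reaction_list(), pars)
  labels <- vapply(net$reactions, function(r) r$label, character(1))
  model <- structure(
    list(network = net,
         arm_tags = arm_tags_main(labels),
         readout_defs = readout_defs_main(),
         free_names = free_parameter_names(),
         kind = "main"),
    class = "signaling_model")
  check_model_integrity(model)
  model
}

#' Extend the model with soluble heparin competition
#'
#' Adds a parallel signaling arm in which FGF captured by soluble heparin
#' (a HSGAG analog) binds FGFR1 to form a weaker heparin-ternary complex that
#' dimerizes (also with the HSGAG-ternary complex), signals to FRS2 and is
#' trafficked like the other bound FGFR1 forms: 26 reactions, 25 species and
#' 3 new rate constants. Because FGF and heparin are supplied from a large,
#' clamped media reservoir, the stimulation protocol applies their solution
#' binding as a pre-equilibrium: free FGF is clamped at
#' `FGF_tot / (1 + [heparin]/Kd_hep)` and the FGF:heparin complex at the
#' remainder (see [simulate()]). With heparin at 0 this reduces exactly to the
#' main model.
#'
#' @param model The main `signaling_model`.
#' @param heparin_ug_per_ml Default heparin dose stored on the model; the
#'   protocol value takes precedence at simulation time.
#' @return Extended `signaling_model` (kind `"heparin"`).
#' @export
build_heparin_extension <- function(model, heparin_ug_per_ml = 500) {
  stopifnot(inherits(model, "signaling_model"))
  if (!identical(model$kind, "main")) stop("expected the main model")
  if (heparin_ug_per_ml < 0) stop("heparin dose must be non-negative")
  net <- model$network
  cmp <- function(...) c(...)
  tch <- cmp(FGF = 1, HEP = 1, FGFR1 = 1)
  dhh <- cmp(FGF = 2, HEP = 2, FGFR1 = 2)
  dhm <- cmp(FGF = 2, HEP = 1, HSGAG = 1, FGFR1 = 2)
  dhhf <- c(dhh, FRS2 = 1)
  dhmf <- c(dhm, FRS2 = 1)
  new_sp <- list(
    species("HEP", "extracellular", 0, TRUE, cmp(HEP = 1)),
    species("FGF_HEP", "extracellular", 0, TRUE, cmp(FGF = 1, HEP = 1)),
    species("TCh", "surface", 0, FALSE, tch),
    species("DCh", "surface", 0, FALSE, dhh),
    species("DCm", "surface", 0, FALSE, dhm),
    species("pDCh", "surface", 0, FALSE, dhh),
    species("pDCm", "surface", 0, FALSE, dhm),
    species("pDCh_FRS2", "surface", 0, FALSE, dhhf),
    species("pDCm_FRS2", "surface", 0, FALSE, dhmf),
    species("pDCh_pFRS2", "surface", 0, FALSE, dhhf),
    species("pDCm_pFRS2", "surface", 0, FALSE, dhmf),
    species("TCh_i", "internal", 0, FALSE, tch),
    species("DCh_i", "internal", 0, FALSE, dhh),
    species("DCm_i", "internal", 0, FALSE, dhm),
    species("pDCh_i", "internal", 0, FALSE, dhh),
    species("pDCm_i", "internal", 0, FALSE, dhm),
    species("pDCh_FRS2_i", "internal", 0, FALSE, dhhf),
    species("pDCm_FRS2_i", "internal", 0, FALSE, dhmf),
    species("TCh_deg", "degraded_pool", 0, FALSE, tch),
    species("DCh_deg", "degraded_pool", 0, FALSE, dhh),
    species("DCm_deg", "degraded_pool", 0, FALSE, dhm),
    species("pDCh_deg", "degraded_pool", 0, FALSE, dhh),
    species("pDCm_deg", "degraded_pool", 0, FALSE, dhm),
    species("pDCh_FRS2_deg", "degraded_pool", 0, FALSE, dhhf),
    species("pDCm_FRS2_deg", "degraded_pool", 0, FALSE, dhmf))
  rx <- function(label, reactants, products, kf, kr = NA) {
    reaction(label, reactants, products, kf, kr)
  }
  new_rx <- list(
    rx("E01", c(FGF = 1, HEP = 1), c(FGF_HEP = 1),
       "kon_FGF_HEP", "koff_FGF_HEP"),
    rx("E02", c(FGF_HEP = 1, FGFR1 = 1), c(TCh = 1), "kon_TCh", "koff_TC"),
    rx("E03", c(TCh = 2), c(DCh = 1), "kon_dim", "koff_dim"),
    rx("E04", c(TCh = 1, TC = 1), c(DCm = 1), "kon_dim", "koff_dim"),
    rx("E05", c(DCh = 1), c(pDCh = 1), "k_phDC", "k_dphDC"),
    rx("E06", c(DCm = 1), c(pDCm = 1), "k_phDC", "k_dphDC"),
    rx("E07", c(pDCh = 1, FRS2 = 1), c(pDCh_FRS2 = 1),
       "kon_pDC_FRS2", "koff_pDC_FRS2"),
    rx("E08", c(pDCm = 1, FRS2 = 1), c(pDCm_FRS2 = 1),
       "kon_pDC_FRS2", "koff_pDC_FRS2"),
    rx("E09", c(pDCh_FRS2 = 1), c(pDCh_pFRS2 = 1), "k_phFRS2"),
    rx("E10", c(pDCm_FRS2 = 1), c(pDCm_pFRS2 = 1), "k_phFRS2"),
    rx("E11", c(pDCh_pFRS2 = 1), c(pDCh = 1, pFRS2 = 1),
       "k_rel_pFRS2", "kon_pDC_FRS2"),
    rx("E12", c(pDCm_pFRS2 = 1), c(pDCm = 1, pFRS2 = 1),
       "k_rel_pFRS2", "kon_pDC_FRS2"))
  n <- 13L
  for (form in c("TCh", "DCh", "DCm", "pDCh", "pDCm",
                 "pDCh_FRS2", "pDCm_FRS2")) {
    new_rx <- c(new_rx, list(
      reaction(sprintf("E%02d", n), setNames(1, form),
               setNames(1, paste0(form, "_i")), "k_intb_R1", "k_recb_R1"),
      reaction(sprintf("E%02d", n + 1L), setNames(1, paste0(form, "_i")),
               setNames(1, paste0(form, "_deg")), "k_degb_R1")))
    n <- n + 2L
  }
  pars <- c(net$parameters, default_heparin_parameters())
  net2 <- reaction_network(c(net$species, new_sp), c(net$reactions, new_rx),
                           pars)
  rd <- model$readout_defs
  rd$pFRS2 <- c(rd$pFRS2, "pDCh_pFRS2", "pDCm_pFRS2")
  new_labels <- vapply(new_rx, function(r) r$label, character(1))
  ext <- structure(
    list(network = net2,
         arm_tags = c(model$arm_tags,
                      setNames(rep("heparin", length(new_labels)), new_labels)),
         readout_defs = rd,
         free_names = model$free_names,
         kind = "heparin",
         heparin_ug_per_ml = heparin_ug_per_ml),
    class = "signaling_model")
  check_model_integrity(ext)
  ext
}

#' Structural integrity check
#'
#' Asserts the declared model sizes (main: 70 reactions / 72 species / 75
#' parameters; heparin extension: +26 / +25 / +3) and that every reaction
#' balances each protein moiety (degraded pools included) - there is no
#' synthesis or loss inside the 2-hour model.
#'
#' @param model A `signaling_model`.
#' @return The model, invisibly; stops with a model-integrity error otherwise.
#' @export
check_model_integrity <- function(model) {
  net <- model$network
  counts <- c(reactions = length(net$reactions),
              species = length(net$species),
              parameters = length(net$parameters))
  want <- if (identical(model$kind, "main")) c(70L, 72L, 75L) else
    c(70L + 26L, 72L + 25L, 75L + 3L)
  if (!all(counts == want)) {
    stop("model-integrity error: counts (reactions/species/parameters) are ",
         paste(counts, collapse = "/"), ", expected ",
         paste(want, collapse = "/"))
  }
  comp <- lapply(net$species, function(s) s$composition)
  names(comp) <- species_names(net)
  side_comp <- function(side) {
    tot <- setNames(numeric(length(PROTEINS)), PROTEINS)
    for (k in seq_along(side)) {
      cc <- comp[[names(side)[k]]]
      tot[names(cc)] <- tot[names(cc)] + side[[k]] * cc
    }
    tot
  }
  for (r in net$reactions) {
    if (!isTRUE(all.equal(side_comp(r$reactants), side_comp(r$products)))) {
      stop("model-integrity error: reaction ", r$label,
           " does not balance protein moieties")
    }
  }
  invisible(model)
}

#' Ligand molecular weights and unit conversion
#'
#' Molecular weights (g/mol) follow the dose pairings used for the training
#' data axes: FGF 25,000 (100 ng/ml = 4 nM) and VEGF 45,455 (50 ng/ml =
#' 1.1 nM). Heparin is assigned a nominal 15,000 g/mol (unfractionated
#' heparin) for converting mass doses to molarity.
#'
#' @param ligand `"FGF"`, `"VEGF"` or `"heparin"`.
#' @return Molecular weight in g/mol.
#' @export
ligand_mw <- function(ligand = c("FGF", "VEGF", "heparin")) {
  ligand <- match.arg(ligand)
  c(FGF = 25000, VEGF = 50 * 1000 / 1.1, heparin = 15000)[[ligand]]
}

#' Convert ligand doses between ng/ml and nM
#'
#' `nM = (ng/ml) * 1000 / MW` and the inverse.
#'
#' @param value Non-negative dose value(s).
#' @param from_unit `"ng_per_ml"` or `"nM"` (also accepts `"ug_per_ml"` for
#'   heparin-style mass doses).
#' @param ligand `"FGF"`, `"VEGF"` or `"heparin"`.
#' @return Converted dose (nM if converting from a mass unit, else ng/ml).
#' @export
ligand_unit_convert <- function(value, from_unit = c("ng_per_ml", "nM",
                                                     "ug_per_ml"),
                                ligand = c("FGF", "VEGF", "heparin")) {
  from_unit <- match.arg(from_unit)
  if (any(value < 0)) stop("dose must be non-negative")
  mw <- ligand_mw(match.arg(ligand))
  switch(from_unit,
         ng_per_ml = value * 1000 / mw,
         ug_per_ml = value * 1e6 / mw,
         nM = value * mw / 1000)
}

#' Extract a readout time series from a trajectory
#'
#' Readouts are sums over species subsets: `pERK_total` sums every free and
#' bound singly- and doubly-phosphorylated ERK species; `pR2_total` sums all
#' phosphorylated VEGFR2 forms (including internalized) except the degraded
#' pool.
#'
#' @param trajectory A [simulate()] result.
#' @param name Readout name (see `model$readout_defs`).
#' @param model The `signaling_model` the trajectory came from.
#' @return `data.frame(time_min, value)` of class `readout_series`.
#' @export
readout <- function(trajectory, name, model) {
  defs <- model$readout_defs
  if (!name %in% names(defs)) stop("unknown readout '", name, "'")
  members <- defs[[name]]
  missing <- setdiff(members, colnames(trajectory$amounts))
  if (length(missing)) {
    stop("trajectory lacks species: ", paste(missing, collapse = ", "))
  }
  val <- rowSums(trajectory$amounts[, members, drop = FALSE])
  structure(data.frame(time_min = trajectory$times, value = val),
            readout = name, class = c("readout_series", "data.frame"))
}

#' Moiety weight vectors from species compositions
#'
#' For each elementary protein, the weight of a species is the number of
#' copies it contains; the weighted total is conserved on any trajectory.
#'
#' @param model A `signaling_model`.
#' @param proteins Which proteins to return (default: all non-ligand).
#' @return Named list of named weight vectors over non-clamped species.
#' @export
moiety_weights <- function(model, proteins = NULL) {
  net <- model$network
  keep <- !vapply(net$species, function(s) s$clamped, logical(1))
  sp <- net$species[keep]
  if (is.null(proteins)) {
    proteins <- setdiff(PROTEINS, c("FGF", "VEGF", "HEP"))
  }
  out <- list()
  for (p in proteins) {
    w <- vapply(sp, function(s) {
      cc <- s$composition
      if (!is.null(cc) && p %in% names(cc)) cc[[p]] else 0
    }, numeric(1))
    names(w) <- vapply(sp, function(s) s$name, character(1))
    w <- w[w != 0]
    if (length(w)) out[[p]] <- w
  }
  out
}
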