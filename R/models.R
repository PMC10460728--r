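#' Physiological system constants
#'
#' Standard adult population values used for in vitro-in vivo scaling and
#' by the PBPK engine. Defaults: liver 1650 g, MPPGL 40 mg/g, hepatic
#' microsomal abundances CYP3A4 137 and CYP2C8 24 pmol/mg (the synthetic
#' pseudo-enzyme `other` has abundance 1 and carries unassigned clearance),
#' hepatic CYP3A4 degradation rate 0.0193 1/h and intestinal 0.029 1/h,
#' hepatic blood flow 97 L/h, villous (mucosal) blood flow 18 L/h,
#' enterocyte volume 0.3 L, total intestinal CYP3A4 66,200 pmol, body
#' weight 70 kg. Between-subject log-normal CVs drive the virtual
#' population (hepatic CL_int 35%, Vss 20%, ka 30%).
#'
#' @param ... Named overrides for any of the default fields.
#' @return An object of class `system_model` (a named list).
#' @export
system_model <- function(...) {
  sys <- list(
    liver_mass = 1650,                 # g
    mppgl = 40,                        # mg microsomal protein / g liver
    enzyme_abundance = c(CYP3A4 = 137, CYP2C8 = 24, other = 1), # pmol/mg
    kdeg = c(liver = 0.0193, gut = 0.029),   # CYP3A4 turnover, 1/h
    hepatic_blood_flow = 97,           # L/h
    villous_blood_flow = 18,           # L/h
    enterocyte_volume = 0.3,           # L
    gut_cyp3a4_amount = 66200,         # pmol, whole small intestine
    body_weight = 70,                  # kg
    population_cv = c(clint = 0.35, vss = 0.20, ka = 0.30)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(sys))
  if (length(bad)) stop("unknown system field(s): ", paste(bad, collapse = ", "))
  sys[names(ov)] <- ov
  num <- unlist(sys[setdiff(names(sys), "population_cv")])
  if (any(num <= 0)) stop("all system constants must be positive")
  structure(sys, class = "system_model")
}

#' Construct a compound parameter set
#'
#' The full parameter record for one compound in the DDI model:
#' physicochemistry and binding, absorption, distribution, per-enzyme
#' hepatic intrinsic clearances (each tagged with the fraction routed to
#' the N-desmethyl metabolite), and interaction parameters (competitive
#' K_i values, calibrated Ind_max/IndC50, P-gp substrate scaling).
#'
#' @param name Compound label.
#' @param mw Molecular weight (g/mol).
#' @param fu Unbound plasma fraction (0-1).
#' @param bp Blood/plasma concentration ratio.
#' @param vss Steady-state distribution volume (L/kg).
#' @param fu_gut Unbound fraction driving gut interactions and gut
#'   metabolism (defaults to `fu`).
#' @param log_p Octanol/water log P (provenance only).
#' @param cl_r Renal plasma clearance (L/h).
#' @param frac_clr_oat3 Fraction of `cl_r` mediated by OAT3 (inhibitable).
#' @param ka First-order absorption rate constant (1/h).
#' @param fa Fraction of dose available for absorption from the lumen.
#' @param vc_frac Fraction of Vss assigned to the central compartment.
#' @param cl_d Inter-compartment distribution clearance (L/h).
#' @param clint_enzyme Named per-enzyme hepatic CL_int (uL/min/pmol; the
#'   pseudo-enzyme `other` is per-pmol against abundance 1).
#' @param frac_to_m2 Named per-enzyme fractions of flux forming the
#'   N-desmethyl metabolite (defaults to 0).
#' @param clint_hlm_additional Additional microsomal CL_int (uL/min/mg).
#' @param ki_cyp3a,ki_pgp,ki_oat3 Competitive inhibition constants
#'   (umol/L unbound; `NA` = no inhibition of that target).
#' @param indmax_calibrated,indc50 CYP3A4 induction parameters (calibrated
#'   fold; umol/L). `indmax_calibrated = 1` means no induction.
#' @param clint_pgp_in_vitro In vitro P-gp efflux intrinsic clearance
#'   (mL/min) scaled to in vivo by `raf_ref`.
#' @param raf_ref P-gp relative activity/expression factor.
#' @param peff_man Effective human jejunal permeability (1e-4 cm/s;
#'   provenance only).
#' @param kp_scalar Tissue-partition scalar (provenance only).
#' @return An object of class `compound_model` (a named list).
#' @export
compound_model <- function(name, mw, fu, bp, vss,
                           fu_gut = fu, log_p = NA_real_,
                           cl_r = 0, frac_clr_oat3 = 0,
                           ka = 1, fa = 0.95, vc_frac = 0.3, cl_d = 10,
                           clint_enzyme = c(other = 0),
                           frac_to_m2 = NULL,
                           clint_hlm_additional = 0,
                           ki_cyp3a = NA_real_, ki_pgp = NA_real_,
                           ki_oat3 = NA_real_,
                           indmax_calibrated = 1, indc50 = 1,
                           clint_pgp_in_vitro = 0, raf_ref = 1,
                           peff_man = NA_real_, kp_scalar = NA_real_) {
  if (mw <= 0) stop("mw must be > 0")
  if (fu <= 0 || fu > 1) stop("fu must be in (0, 1]")
  if (any(clint_enzyme < 0)) stop("clint entries must be >= 0")
  if (fa <= 0 || fa > 1) stop("fa must be in (0, 1]")
  if (clint_pgp_in_vitro > 0 && raf_ref <= 0)
    stop("raf_ref must be > 0 for a P-gp substrate")
  if (is.null(frac_to_m2))
    frac_to_m2 <- setNames(rep(0, length(clint_enzyme)), names(clint_enzyme))
  if (any(frac_to_m2 < 0 | frac_to_m2 > 1))
    stop("frac_to_m2 entries must lie in [0, 1]")
  structure(list(
    name = name, mw = mw, fu = fu, fu_gut = fu_gut, bp = bp, vss = vss,
    log_p = log_p, cl_r = cl_r, frac_clr_oat3 = frac_clr_oat3,
    ka = ka, fa = fa, vc_frac = vc_frac, cl_d = cl_d,
    clint_enzyme = clint_enzyme, frac_to_m2 = frac_to_m2,
    clint_hlm_additional = clint_hlm_additional,
    ki_cyp3a = ki_cyp3a, ki_pgp = ki_pgp, ki_oat3 = ki_oat3,
    indmax_calibrated = indmax_calibrated, indc50 = indc50,
    clint_pgp_in_vitro = clint_pgp_in_vitro, raf_ref = raf_ref,
    peff_man = peff_man, kp_scalar = kp_scalar), class = "compound_model")
}

#' Enzalutamide perpetrator model
#'
#' Parameterized from clinical and in vitro data: oral clearance 0.60 L/h
#' split 87% CYP2C8 / 13% CYP3A4 by the retrograde method (per-pmol values
#' 0.1518 + 0.07475 and 0.002312 + 0.003617 uL/min/pmol, the first entry
#' of each pair forming the N-desmethyl metabolite), fu 0.0244, B/P 0.55,
#' Vss 0.967 L/kg, calibrated CYP3A4 Ind_max 11.43 with IndC50 1.5 umol/L,
#' K_i 42 (CYP3A4), 1.67 (P-gp) and 15.1 (OAT3) umol/L. The absorption
#' constants (ka 1.4 1/h, fa 0.95) are package choices giving the observed
#' 1-2 h time to peak; enzalutamide is not a P-gp substrate.
#'
#' @return A [compound_model()].
#' @export
enzalutamide_model <- function() {
  compound_model(
    name = "enzalutamide", mw = 464.44, log_p = 2.98,
    fu = 0.0244, bp = 0.55, vss = 0.967, kp_scalar = 0.933,
    cl_r = 0, ka = 1.4, fa = 0.95, peff_man = 5.15,
    clint_enzyme = c(CYP2C8 = 0.1518 + 0.07475,
                     CYP3A4 = 0.002312 + 0.003617),
    frac_to_m2 = c(CYP2C8 = 0.1518 / (0.1518 + 0.07475),
                   CYP3A4 = 0.002312 / (0.002312 + 0.003617)),
    ki_cyp3a = 42, ki_pgp = 1.67, ki_oat3 = 15.1,
    indmax_calibrated = 11.43, indc50 = 1.5)
}

#' N-desmethyl enzalutamide (M2) metabolite model
#'
#' The active metabolite, formed hepatically from enzalutamide and itself
#' a CYP3A4 inducer and P-gp/OAT3 inhibitor: fu 0.0467, B/P 0.55, Vss
#' 0.48 L/kg, CYP3A4 CL_int 0.001075 uL/min/pmol plus additional
#' microsomal clearance 1.399 uL/min/mg (CYP3A4 therefore ~9% of its
#' elimination), calibrated Ind_max 9.72 with IndC50 2.5 umol/L, K_i 1.09
#' (P-gp) and 11.5 (OAT3) umol/L.
#'
#' @return A [compound_model()].
#' @export
m2_model <- function() {
  compound_model(
    name = "M2", mw = 450.41, log_p = 2.11,
    fu = 0.0467, bp = 0.55, vss = 0.48,
    cl_r = 0, ka = 1.4, fa = 0.95,
    clint_enzyme = c(CYP3A4 = 0.001075),
    clint_hlm_additional = 1.399,
    ki_pgp = 1.09, ki_oat3 = 11.5,
    indmax_calibrated = 9.72, indc50 = 2.5)
}

#' Approximate victim compound models
#'
#' Minimal, declared-approximate parameter files for the victim drugs.
#' They are assembled from public clinical PK constants plus the stated
#' CYP3A metabolic fractions (apixaban 42%, rivaroxaban 61%) and default
#' intestinal P-gp RAF/REF values (apixaban 25, rivaroxaban 0.15); they
#' are not the proprietary library models, and simulated interaction
#' ratios built on them are qualitative.
#'
#' * `digoxin`: renally cleared P-gp probe (fu 0.71, Vss 6.7 L/kg, CL_R
#'   6.6 L/h, small non-CYP3A hepatic clearance, strong intestinal efflux).
#' * `midazolam`: high fm_CYP3A hepatic + gut CYP3A probe (fu 0.032,
#'   B/P 0.66, fm_CYP3A 0.94, fu_gut 1).
#' * `apixaban`: fm_CYP3A 0.42, CL_R 0.9 of 3.3 L/h, P-gp RAF/REF 25.
#' * `rivaroxaban`: fm_CYP3A 0.61, CL_R 3.3 of 10 L/h, P-gp RAF/REF 0.15;
#'   `model = 1` routes half of renal clearance through inhibitable OAT3,
#'   `model = 2` has no OAT3 component.
#'
#' @param name One of `"digoxin"`, `"midazolam"`, `"apixaban"`,
#'   `"rivaroxaban"`.
#' @param model Rivaroxaban renal-elimination variant (1 = OAT3 involved,
#'   2 = not).
#' @param raf_ref Optional override of the intestinal P-gp RAF/REF.
#' @param system A [system_model()] used to convert clearances to
#'   intrinsic clearances (well-stirred inversion).
#' @return A [compound_model()].
#' @export
victim_model <- function(name = c("digoxin", "midazolam", "apixaban",
                                  "rivaroxaban"),
                         model = 1, raf_ref = NULL,
                         system = system_model()) {
  name <- match.arg(name)
  # split a hepatic plasma clearance into per-pmol clint by fm (well-stirred)
  clint_split <- function(cl_h, fu, bp, fm) {
    q <- system$hepatic_blood_flow
    cl_b <- cl_h / bp
    if (cl_b >= q) stop("hepatic clearance exceeds liver blood flow")
    clint_u <- q * cl_b / ((fu / bp) * (q - cl_b))      # L/h unbound
    per_mg <- clint_u * 1e6 / 60 / (system$liver_mass * system$mppgl)
    per_mg * fm / system$enzyme_abundance[names(fm)]
  }
  cmp <- switch(name,
    digoxin = compound_model(
      name = "digoxin", mw = 780.9, fu = 0.71, bp = 1.0, vss = 6.7,
      fu_gut = 1, cl_r = 6.6, ka = 1.0, fa = 0.9, cl_d = 40,
      clint_enzyme = clint_split(1.4, 0.71, 1.0, c(other = 1)),
      clint_pgp_in_vitro = 850, raf_ref = 1),
    midazolam = compound_model(
      name = "midazolam", mw = 325.8, fu = 0.032, bp = 0.66, vss = 1.0,
      fu_gut = 1, cl_r = 0, ka = 2.0, fa = 0.95,
      clint_enzyme = clint_split(27, 0.032, 0.66,
                                 c(CYP3A4 = 0.94, other = 0.06))),
    apixaban = compound_model(
      name = "apixaban", mw = 459.5, fu = 0.13, bp = 0.9, vss = 0.30,
      cl_r = 0.9, ka = 0.6, fa = 0.9,
      clint_enzyme = clint_split(2.4, 0.13, 0.9,
                                 c(CYP3A4 = 0.42, other = 0.58)),
      clint_pgp_in_vitro = 92, raf_ref = 25),
    rivaroxaban = compound_model(
      name = "rivaroxaban", mw = 435.9, fu = 0.07, bp = 0.7, vss = 0.70,
      cl_r = 3.3, frac_clr_oat3 = if (model == 1) 0.5 else 0,
      ka = 1.0, fa = 0.9,
      clint_enzyme = clint_split(6.7, 0.07, 0.7,
                                 c(CYP3A4 = 0.61, other = 0.39)),
      clint_pgp_in_vitro = 92, raf_ref = 0.15))
  if (!is.null(raf_ref)) cmp$raf_ref <- raf_ref
  cmp
}

#' Dosing regimen
#'
#' @param compound Compound label (must match a compound in the model).
#' @param dose Dose (mg), > 0.
#' @param interval Dosing interval (h); required when `n_doses > 1`.
#' @param n_doses Number of doses.
#' @param start Time of the first dose (h).
#' @return An object of class `regimen`.
#' @export
regimen <- function(compound, dose, interval = 24, n_doses = 1, start = 0) {
  if (dose <= 0) stop("dose must be > 0")
  if (n_doses > 1 && interval <= 0) stop("interval must be > 0")
  structure(list(compound = compound, dose = dose, interval = interval,
                 n_doses = n_doses, start = start), class = "regimen")
}

#' Assemble a simulation model specification
#'
#' Binds a system, a set of compounds, perpetrator/victim/metabolite roles
#' and the interaction switches into one object consumed by
#' [simulate_pbpk()].
#'
#' @param system A [system_model()].
#' @param compounds List of [compound_model()]s.
#' @param perpetrators Character vector of compounds whose concentrations
#'   drive induction/inhibition.
#' @param metabolite_links List of `list(parent=, metabolite=)` pairs; the
#'   parent's `frac_to_m2` fractions route its hepatic flux into the
#'   metabolite's central compartment (mole-conserving).
#' @param switches Named logical/numeric interaction switches:
#'   `cyp3a_induction`, `cyp3a_inhibition`, `pgp_inhibition`,
#'   `oat3_inhibition` (logical) and `pgp_fold_increase` (static FI
#'   multiplier on intestinal P-gp expression, default 1 = no induction).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(system = system_model(), compounds,
                       perpetrators = character(),
                       metabolite_links = list(),
                       switches = list()) {
  defaults <- list(cyp3a_induction = TRUE, cyp3a_inhibition = TRUE,
                   pgp_inhibition = TRUE, oat3_inhibition = TRUE,
                   pgp_fold_increase = 1)
  bad <- setdiff(names(switches), names(defaults))
  if (length(bad)) stop("unknown switch(es): ", paste(bad, collapse = ", "))
  defaults[names(switches)] <- switches
  if (defaults$pgp_fold_increase <= 0) stop("pgp_fold_increase must be > 0")
  nm <- vapply(compounds, `[[`, "", "name")
  names(compounds) <- nm
  if (anyDuplicated(nm)) stop("duplicate compound names")
  if (!all(perpetrators %in% nm)) stop("unknown perpetrator compound")
  for (lk in metabolite_links)
    if (!all(c(lk$parent, lk$metabolite) %in% nm))
      stop("metabolite link references unknown compound")
  structure(list(system = system, compounds = compounds,
                 perpetrators = perpetrators,
                 metabolite_links = metabolite_links,
                 switches = defaults), class = "model_spec")
}
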