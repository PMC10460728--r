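#' Retrograde intrinsic clearance calculation
#'
#' Distributes an observed in vivo oral clearance over metabolic pathways
#' and scales it down to per-pmol-enzyme intrinsic clearances. By default
#' the low-extraction-ratio limit `CL_po = fu * CL_int,u` is inverted
#' directly (appropriate for drugs like enzalutamide whose hepatic
#' extraction is a few percent); `well_stirred = TRUE` instead inverts the
#' full well-stirred oral-clearance relation
#' `CL_po = fu/BP * CL_int` referenced through blood (identical in the
#' low-extraction limit, and requiring `bp` and the hepatic blood flow).
#'
#' The total unbound intrinsic clearance (L/h) is converted to
#' uL/min/mg microsomal protein via liver mass x MPPGL, split by the
#' fractional pathway contributions `fm`, and divided by each enzyme's
#' microsomal abundance to give uL/min/pmol.
#'
#' @param cl_po Observed oral plasma clearance (L/h), > 0. For
#'   `well_stirred = TRUE` this is still the oral (not systemic) clearance,
#'   for which `CL_po = fu_b * CL_int` holds at any extraction ratio.
#' @param fu Unbound plasma fraction (0-1).
#' @param fm Named numeric vector of fractional enzyme contributions,
#'   summing to 1.
#' @param system A [system_model()] providing liver mass, MPPGL and enzyme
#'   abundances.
#' @param bp Blood/plasma ratio, used only when `well_stirred = TRUE`.
#' @param well_stirred Reference the unbound clearance through blood
#'   (`fu/bp`) rather than plasma.
#' @return Named numeric vector of per-enzyme CL_int (uL/min/pmol enzyme).
#' @examples
#' retrograde_clint(0.60, 0.0244, c(CYP2C8 = 0.87, CYP3A4 = 0.13))
#' @export
retrograde_clint <- function(cl_po, fu, fm, system = system_model(),
                             bp = 1, well_stirred = FALSE) {
  if (cl_po <= 0) stop("cl_po must be > 0")
  if (fu <= 0 || fu > 1) stop("fu must be in (0, 1]")
  if (abs(sum(fm) - 1) > 1e-9) stop("fm must sum to 1")
  miss <- setdiff(names(fm), names(system$enzyme_abundance))
  if (length(miss))
    stop("no abundance configured for enzyme(s): ", paste(miss, collapse = ", "))
  fu_ref <- if (well_stirred) fu / bp else fu
  clint_u_total <- cl_po / fu_ref                       # L/h, unbound
  mg_microsomes <- system$liver_mass * system$mppgl     # mg protein
  per_mg <- clint_u_total * 1e6 / 60 / mg_microsomes    # uL/min/mg
  per_mg * fm / system$enzyme_abundance[names(fm)]
}

#' Forward reconstruction of oral clearance from per-pmol CL_int
#'
#' Inverse of [retrograde_clint()]: sums per-enzyme intrinsic clearances
#' back up through abundance, MPPGL and liver mass and multiplies by the
#' unbound fraction.
#'
#' @inheritParams retrograde_clint
#' @param clint Named per-enzyme CL_int (uL/min/pmol).
#' @return Oral plasma clearance (L/h).
#' @export
forward_cl_po <- function(clint, fu, system = system_model(),
                          bp = 1, well_stirred = FALSE) {
  ab <- system$enzyme_abundance[names(clint)]
  per_mg <- sum(clint * ab)                             # uL/min/mg
  clint_u_total <- per_mg * system$liver_mass * system$mppgl * 60 / 1e6
  fu_ref <- if (well_stirred) fu / bp else fu
  fu_ref * clint_u_total
}

#' Fractional enzyme contributions from per-pmol CL_int
#'
#' `fm(e) = clint(e) * abundance(e) / sum over enzymes` - the fraction of
#' total hepatic intrinsic clearance carried by each enzyme.
#'
#' @param clint Named per-enzyme CL_int (uL/min/pmol).
#' @param abundance Named enzyme abundances (pmol/mg microsomal protein)
#'   over the same enzymes.
#' @return Named numeric vector of fractions summing to 1.
#' @examples
#' fm_from_clint(c(CYP2C8 = 0.22655, CYP3A4 = 0.005929),
#'               c(CYP2C8 = 24, CYP3A4 = 137))
#' @export
fm_from_clint <- function(clint, abundance) {
  if (!length(clint)) stop("empty clint map")
  if (!setequal(names(clint), names(abundance)))
    stop("clint and abundance must cover the same enzymes")
  w <- clint * abundance[names(clint)]
  w / sum(w)
}

#' Solve a secondary pathway's metabolite-formation fraction
#'
#' Given that the primary pathway carries `fm_primary` of total intrinsic
#' clearance and routes `frac_primary` of its flux to the metabolite,
#' finds the fraction `x` of the secondary pathway's flux that must form
#' the metabolite so the overall conversion equals `target_overall`:
#' `fm_primary * frac_primary + (1 - fm_primary) * x = target_overall`.
#'
#' @param fm_primary Fraction of total CL_int on the primary pathway (< 1).
#' @param frac_primary Fraction of the primary pathway forming the
#'   metabolite (0-1).
#' @param target_overall Required overall fraction of dose converted.
#' @return The secondary pathway's metabolite-formation fraction, in [0,1].
#' @examples
#' split_to_metabolite(0.87, 0.67, 0.6336) # ~0.39
#' @export
split_to_metabolite <- function(fm_primary, frac_primary, target_overall) {
  if (fm_primary >= 1) stop("fm_primary must be < 1")
  x <- (target_overall - fm_primary * frac_primary) / (1 - fm_primary)
  if (x < -1e-12 || x > 1 + 1e-12)
    stop(sprintf("infeasible: required secondary fraction %.3f outside [0, 1]", x))
  min(max(x, 0), 1)
}

#' Overall metabolite-formation fraction of a pathway split
#'
#' `sum over enzymes of fm(e) * frac_to_metabolite(e)`.
#'
#' @param fm Named fractional enzyme contributions (sum to 1).
#' @param frac_to_metabolite Named per-enzyme metabolite-formation
#'   fractions over the same enzymes, each in [0, 1].
#' @return Overall fraction of eliminated drug converted to the metabolite.
#' @examples
#' overall_to_metabolite(c(CYP2C8 = 0.87, CYP3A4 = 0.13),
#'                       c(CYP2C8 = 0.67, CYP3A4 = 0.39)) # 0.6336
#' @export
overall_to_metabolite <- function(fm, frac_to_metabolite) {
  if (abs(sum(fm) - 1) > 1e-9) stop("fm must sum to 1")
  f <- frac_to_metabolite[names(fm)]
  if (any(f < 0 | f > 1)) stop("frac_to_metabolite must lie in [0, 1]")
  sum(fm * f)
}

#' CYP3A4 contribution to a metabolite's elimination
#'
#' Fraction of total hepatic intrinsic clearance carried by CYP3A4 when the
#' remainder is an unassigned microsomal clearance:
#' `clint_3a4 * abundance / (clint_3a4 * abundance + clint_hlm_additional)`
#' with the CYP3A4 term in uL/min/pmol x pmol/mg and the additional term
#' already in uL/min/mg.
#'
#' @param clint_3a4 CYP3A4 CL_int (uL/min/pmol enzyme).
#' @param clint_hlm_additional Additional microsomal CL_int (uL/min/mg).
#' @param abundance_3a4 CYP3A4 abundance (pmol/mg), default from
#'   [system_model()].
#' @return Fraction in [0, 1].
#' @examples
#' m2_cyp3a4_fraction(0.001075, 1.399) # ~0.095
#' @export
m2_cyp3a4_fraction <- function(clint_3a4, clint_hlm_additional,
                               abundance_3a4 = system_model()$enzyme_abundance[["CYP3A4"]]) {
  if (clint_3a4 < 0 || clint_hlm_additional < 0 || abundance_3a4 <= 0)
    stop("inputs must be non-negative (abundance > 0)")
  den <- clint_3a4 * abundance_3a4 + clint_hlm_additional
  if (den == 0) stop("all-zero clearance: fraction undefined")
  clint_3a4 * abundance_3a4 / den
}
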