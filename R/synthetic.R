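#' Generate a synthetic hepatocyte induction dataset
#'
#' Lot-level fold inductions are the concentration-response model value
#' times a log-normal deviate (mean 1, coefficient of variation
#' `lot_cv`), emulating between-lot variability of hepatocyte assays whose
#' reported SDs scale with the means. Means and SDs over lots are
#' returned in the same layout as [induction_table()], alongside the
#' generating truth.
#'
#' @param ind_max,ind_c50 True induction parameters.
#' @param concentrations Tested concentrations (umol/L), positive; the
#'   default is the three-concentration assay design (1, 10, 100).
#' @param n_lots Hepatocyte lots per concentration (default 3).
#' @param lot_cv Between-lot coefficient of variation (default 0.33, the
#'   scale of the assay's reported CYP3A4 SD/mean).
#' @param seed Integer seed; regeneration from the same seed is
#'   bit-identical.
#' @param compound,gene Labels written into the dataset.
#' @return List with `data` (a data.frame passing the induction-table
#'   schema), `lots` (lot-level folds) and `truth`.
#' @export
gen_induction_dataset <- function(ind_max, ind_c50,
                                  concentrations = c(1, 10, 100),
                                  n_lots = 3, lot_cv = 0.33, seed = 1,
                                  compound = "synthetic", gene = "CYP3A4") {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (n_lots < 1) stop("n_lots must be >= 1")
  set.seed(seed)
  sdlog <- sqrt(log(1 + lot_cv^2))
  mu <- fold_induction_model(concentrations, ind_max, ind_c50)
  lots <- vapply(mu, function(m)
    m * stats::rlnorm(n_lots, meanlog = -sdlog^2 / 2, sdlog = sdlog),
    numeric(n_lots))
  lots <- matrix(lots, nrow = n_lots)
  d <- data.frame(compound = compound, gene = gene,
                  concentration_umol_L = concentrations,
                  fold_mean = colMeans(lots),
                  fold_sd = if (n_lots > 1) apply(lots, 2, stats::sd)
                            else NA_real_,
                  n_lots = n_lots)
  validate_induction_table(d)
  list(data = d, lots = lots,
       truth = list(generator = "gen_induction_dataset", ind_max = ind_max,
                    ind_c50 = ind_c50, lot_cv = lot_cv, seed = seed))
}

#' Generate a synthetic bidirectional transwell dataset
#'
#' Builds directional P_app series for control and MDR1-expressing
#' monolayers consistent with a Hill inhibition curve: the MDR1
#' basal-to-apical P_app falls (and apical-to-basal rises) with inhibitor
#' concentration so that the corrected efflux ratio follows
#' `baseline_ratio * (1 - i_max * I^C / (I^C + ic50^C))`, while control
#' ratios stay near 1. Measurement noise is truncated normal (3 SD) so
#' P_app stays positive.
#'
#' @param ic50,i_max,hill_c True inhibition parameters.
#' @param baseline_ratio Corrected efflux ratio without inhibitor (> 1).
#' @param concentrations Inhibitor concentrations including 0.
#' @param noise_cv Measurement CV on each P_app (default 0.06, the scale
#'   of the assay's replicate SDs).
#' @param seed Integer seed.
#' @param additive Label written into the dataset.
#' @return List with `data` (a data.frame passing the transwell-table
#'   schema) and `truth`.
#' @export
gen_transwell_dataset <- function(ic50, i_max, hill_c, baseline_ratio = 20,
                                  concentrations = c(0, 0.3, 1, 3, 10, 30, 50),
                                  noise_cv = 0.06, seed = 1,
                                  additive = "synthetic") {
  if (baseline_ratio <= 1) stop("baseline corrected ratio must be > 1")
  set.seed(seed)
  papp_ctl_a2b <- 1.6; papp_ctl_b2a <- 1.6      # passive, direction-symmetric
  noisy <- function(m) {
    z <- pmax(pmin(stats::rnorm(length(m)), 3), -3)
    m * (1 + noise_cv * z)
  }
  rows <- lapply(concentrations, function(cn) {
    ratio <- baseline_ratio *
      (1 - i_max * if (cn > 0) cn^hill_c / (cn^hill_c + ic50^hill_c) else 0)
    ratio <- max(ratio, 1)
    # split the efflux ratio symmetrically between the two directions
    m_a2b <- papp_ctl_a2b / sqrt(ratio)
    m_b2a <- papp_ctl_b2a * sqrt(ratio)
    data.frame(cell_line = rep(c("control", "control", "MDR1", "MDR1"), 1),
               additive = additive, additive_conc_umol_L = cn,
               direction = c("A2B", "B2A", "A2B", "B2A"),
               papp_1e6_cm_s = noisy(c(papp_ctl_a2b, papp_ctl_b2a,
                                       m_a2b, m_b2a)),
               papp_sd_1e6_cm_s = NA_real_)
  })
  d <- do.call(rbind, rows)
  validate_transwell_table(d)
  list(data = d,
       truth = list(generator = "gen_transwell_dataset", ic50 = ic50,
                    i_max = i_max, hill_c = hill_c,
                    baseline_ratio = baseline_ratio, noise_cv = noise_cv,
                    seed = seed))
}

#' Generate a random but valid victim compound
#'
#' Draws a victim parameter set from plausible ranges for property-based
#' engine tests: CYP3A metabolic fraction, P-gp scaling, renal clearance,
#' distribution volume and absorption rate.
#'
#' @param seed Integer seed.
#' @param fm_cyp3a Optional fixed CYP3A fraction (otherwise uniform 0-0.95).
#' @param system A [system_model()].
#' @return A [compound_model()] with attribute `truth` recording the draw.
#' @export
gen_victim_compound <- function(seed = 1, fm_cyp3a = NULL,
                                system = system_model()) {
  set.seed(seed)
  fm3 <- if (is.null(fm_cyp3a)) stats::runif(1, 0, 0.95) else fm_cyp3a
  cl_h <- stats::runif(1, 1, 30)        # L/h hepatic plasma clearance
  fu <- stats::runif(1, 0.02, 0.9)
  bp <- stats::runif(1, 0.6, 1.2)
  vss <- stats::runif(1, 0.2, 4)
  ka <- stats::runif(1, 0.4, 2)
  cl_r <- stats::runif(1, 0, 5)
  raf <- stats::runif(1, 0.1, 30)
  clint_pgp <- stats::runif(1, 0, 200)
  q <- system$hepatic_blood_flow
  cl_b <- min(cl_h / bp, 0.8 * q)
  clint_u <- q * cl_b / ((fu / bp) * (q - cl_b))
  per_mg <- clint_u * 1e6 / 60 / (system$liver_mass * system$mppgl)
  fm <- c(CYP3A4 = fm3, other = 1 - fm3)
  cm <- compound_model(
    name = paste0("victim_seed", seed), mw = 400, fu = fu, bp = bp,
    vss = vss, cl_r = cl_r, ka = ka, fa = 0.9,
    clint_enzyme = per_mg * fm / system$enzyme_abundance[names(fm)],
    clint_pgp_in_vitro = clint_pgp, raf_ref = raf)
  attr(cm, "truth") <- list(generator = "gen_victim_compound", seed = seed,
                            fm_cyp3a = fm3, cl_h = cl_h, fu = fu, bp = bp,
                            vss = vss, ka = ka, cl_r = cl_r, raf_ref = raf,
                            clint_pgp_in_vitro = clint_pgp)
  cm
}
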