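#' Define a perpetrator-victim DDI study scenario
#'
#' Default design: enzalutamide 160 mg once daily for 50 days, then a
#' single victim dose co-administered at the start of day 51 while
#' perpetrator dosing continues; victim exposure is measured over a
#' post-dose window in both arms (victim alone vs victim + perpetrator)
#' with identical subject parameters (paired design).
#'
#' @param victim Victim name accepted by [victim_model()], or a
#'   [compound_model()] of your own.
#' @param victim_dose Victim dose (mg). Defaults per drug: digoxin 0.25,
#'   midazolam 2, apixaban 10, rivaroxaban 20.
#' @param perp_dose Perpetrator dose (mg), default 160 once daily.
#' @param pretreat_days Days of perpetrator dosing before the victim dose
#'   (default 50).
#' @param window Victim exposure window after its dose (h, default 120).
#' @param fi_pgp Static fold-increase in intestinal P-gp expression
#'   (default 1 = no induction).
#' @param raf_ref_override Optional override of the victim's intestinal
#'   P-gp RAF/REF.
#' @param rivaroxaban_model 1 (OAT3 in renal elimination) or 2 (not).
#' @param switches Named overrides of the interaction switches (see
#'   [model_spec()]); `fi_pgp` sets `pgp_fold_increase`.
#' @param n_subjects Virtual-population size (default 100).
#' @param seed Population seed.
#' @param system A [system_model()].
#' @param solver_opts Passed to [simulate_pbpk()].
#' @return An object of class `ddi_scenario`.
#' @export
ddi_scenario <- function(victim, victim_dose = NULL, perp_dose = 160,
                         pretreat_days = 50, window = 120,
                         fi_pgp = 1, raf_ref_override = NULL,
                         rivaroxaban_model = 1, switches = list(),
                         n_subjects = 100, seed = 20230601,
                         system = system_model(), solver_opts = list()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (fi_pgp <= 0) stop("fi_pgp must be > 0")
  if (is.character(victim)) {
    default_dose <- c(digoxin = 0.25, midazolam = 2, apixaban = 10,
                      rivaroxaban = 20)[[victim]]
    vic <- victim_model(victim, model = rivaroxaban_model, system = system)
  } else {
    vic <- victim
    default_dose <- NULL
  }
  if (is.null(victim_dose)) victim_dose <- default_dose
  if (is.null(victim_dose)) stop("victim_dose required for custom victims")
  if (!is.null(raf_ref_override)) vic$raf_ref <- raf_ref_override
  sw <- utils::modifyList(list(pgp_fold_increase = fi_pgp), switches)
  structure(list(victim = vic, victim_dose = victim_dose,
                 perp_dose = perp_dose, pretreat_days = pretreat_days,
                 window = window, switches = sw,
                 n_subjects = n_subjects, seed = seed, system = system,
                 solver_opts = solver_opts), class = "ddi_scenario")
}

# Apply between-subject log-normal multipliers to a compound (shared
# subject physiology: one hepatic CL_int, one Vss and one ka multiplier).
apply_subject <- function(cm, mult) {
  cm$clint_enzyme <- cm$clint_enzyme * mult[["clint"]]
  cm$clint_hlm_additional <- cm$clint_hlm_additional * mult[["clint"]]
  cm$vss <- cm$vss * mult[["vss"]]
  cm$ka <- cm$ka * mult[["ka"]]
  cm
}

simulate_arms <- function(scenario, mult = c(clint = 1, vss = 1, ka = 1)) {
  sc <- scenario
  vic <- apply_subject(sc$victim, mult)
  enz <- apply_subject(enzalutamide_model(), mult)
  m2 <- apply_subject(m2_model(), mult)
  t_vic <- sc$pretreat_days * 24
  dur <- t_vic + sc$window

  # victim alone: no perpetrator present, enzyme pools and intestinal
  # P-gp expression at baseline (the fold increase is perpetrator-induced)
  sw0 <- sc$switches
  sw0$pgp_fold_increase <- 1
  spec0 <- model_spec(sc$system, list(vic), switches = sw0)
  r0 <- regimen(vic$name, sc$victim_dose, start = 0)
  sim0 <- simulate_pbpk(spec0, list(r0), sc$window,
                        solver_opts = sc$solver_opts)
  m0 <- pk_metrics(sim0, vic$name, c(0, sc$window))

  # victim + perpetrator at steady state
  spec1 <- model_spec(sc$system, list(enz, m2, vic),
                      perpetrators = c("enzalutamide", "M2"),
                      metabolite_links = list(
                        list(parent = "enzalutamide", metabolite = "M2")),
                      switches = sc$switches)
  n_perp_doses <- sc$pretreat_days + ceiling(sc$window / 24)
  r_perp <- regimen("enzalutamide", sc$perp_dose, interval = 24,
                    n_doses = n_perp_doses, start = 0)
  r_vic <- regimen(vic$name, sc$victim_dose, start = t_vic)
  sim1 <- simulate_pbpk(spec1, list(r_perp, r_vic), dur,
                        solver_opts = sc$solver_opts)
  m1 <- pk_metrics(sim1, vic$name, c(t_vic, dur))

  list(without = m0, with = m1,
       auc_ratio = m1$auc / m0$auc, cmax_ratio = m1$cmax / m0$cmax)
}

#' Run a population DDI simulation
#'
#' Simulates each virtual subject's victim exposure with and without the
#' perpetrator under identical subject parameters, and summarizes the
#' paired AUC and Cmax ratios as geometric mean ratios with t-based 90%
#' confidence intervals on the log scale. Subject variability is
#' log-normal on hepatic CL_int, Vss and ka with the system's population
#' CVs. Fixed seed, fixed subject order: bit-reproducible.
#'
#' @param scenario A [ddi_scenario()].
#' @return An object of class `ddi_result`: list with `auc_ratio_gmr`,
#'   `cmax_ratio_gmr`, `ci90_auc`, `ci90_cmax`, `per_subject` data.frame,
#'   `n_excluded`.
#' @export
run_ddi <- function(scenario) {
  sc <- scenario
  cv <- sc$system$population_cv
  draws <- if (sc$n_subjects > 1) {
    set.seed(sc$seed)
    sdlog <- sqrt(log(1 + cv^2))
    matrix(stats::rlnorm(3 * sc$n_subjects,
                         meanlog = rep(-sdlog^2 / 2, sc$n_subjects),
                         sdlog = rep(sdlog, sc$n_subjects)),
           ncol = 3, byrow = TRUE,
           dimnames = list(NULL, names(cv)))
  } else matrix(1, 1, 3, dimnames = list(NULL, names(cv)))

  rows <- lapply(seq_len(sc$n_subjects), function(s) {
    arms <- simulate_arms(sc, draws[s, ])
    data.frame(subject = s, auc_ratio = arms$auc_ratio,
               cmax_ratio = arms$cmax_ratio,
               auc_without = arms$without$auc, auc_with = arms$with$auc)
  })
  per <- do.call(rbind, rows)
  ok <- is.finite(per$auc_ratio) & per$auc_ratio > 0 &
    is.finite(per$cmax_ratio) & per$cmax_ratio > 0
  n_excl <- sum(!ok)
  if (n_excl) warning(n_excl, " subject(s) with non-positive exposure excluded")
  per_ok <- per[ok, ]
  g_auc <- gmr_ci(per_ok$auc_ratio)
  g_cmax <- gmr_ci(per_ok$cmax_ratio)
  structure(list(auc_ratio_gmr = g_auc[["gmr"]],
                 cmax_ratio_gmr = g_cmax[["gmr"]],
                 ci90_auc = g_auc[c("lower", "upper")],
                 ci90_cmax = g_cmax[c("lower", "upper")],
                 per_subject = per, n_excluded = n_excl),
            class = "ddi_result")
}

#' @export
print.ddi_result <- function(x, ...) {
  cat(sprintf("DDI result over %d subjects (%d excluded):\n",
              nrow(x$per_subject), x$n_excluded))
  cat(sprintf("  AUC ratio GMR  %.3f (90%% CI %.3f-%.3f)\n",
              x$auc_ratio_gmr, x$ci90_auc[[1]], x$ci90_auc[[2]]))
  cat(sprintf("  Cmax ratio GMR %.3f (90%% CI %.3f-%.3f)\n",
              x$cmax_ratio_gmr, x$ci90_cmax[[1]], x$ci90_cmax[[2]]))
  invisible(x)
}

#' Geometric mean ratio with t-based confidence interval
#'
#' @param ratios Positive ratio series.
#' @param level Confidence level (default 0.90).
#' @return Named vector `gmr`, `lower`, `upper`. With a single ratio the
#'   interval is degenerate at the point estimate.
#' @export
gmr_ci <- function(ratios, level = 0.90) {
  if (any(ratios <= 0) || any(!is.finite(ratios)))
    stop("ratios must be positive and finite")
  lr <- log(ratios)
  m <- mean(lr)
  n <- length(lr)
  if (n < 2 || stats::sd(lr) == 0)
    return(c(gmr = exp(m), lower = exp(m), upper = exp(m)))
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(lr) / sqrt(n)
  c(gmr = exp(m), lower = exp(m - half), upper = exp(m + half))
}

#' Acceptance interval for a predicted DDI ratio (Guest measure)
#'
#' Observation-scaled acceptance bounds with a variability term `delta`:
#' with `R` the observed ratio (reciprocal taken when below 1),
#' `L = (delta + 2 (R - 1)) / R` and the interval is `[R / L, R * L]`,
#' mapped back through the reciprocal when the observed ratio is below 1.
#' At `R = 1` the interval is the classical `[1/delta, delta]`.
#'
#' @param observed_ratio Observed geometric mean ratio, > 0.
#' @param delta Variability term (>= 1, default 1.25).
#' @return An object of class `guest_bounds`: list with `observed_ratio`,
#'   `delta`, `lower`, `upper`.
#' @examples
#' guest_bounds(1.29) # 0.91-1.83
#' @export
guest_bounds <- function(observed_ratio, delta = 1.25) {
  if (observed_ratio <= 0) stop("observed_ratio must be > 0")
  if (delta < 1) stop("delta must be >= 1")
  r <- if (observed_ratio < 1) 1 / observed_ratio else observed_ratio
  l <- (delta + 2 * (r - 1)) / r
  b <- c(r / l, r * l)
  if (observed_ratio < 1) b <- rev(1 / b)
  structure(list(observed_ratio = observed_ratio, delta = delta,
                 lower = b[1], upper = b[2]), class = "guest_bounds")
}

#' @export
print.guest_bounds <- function(x, ...) {
  cat(sprintf("Guest acceptance interval for observed ratio %.3g: %.2f-%.2f\n",
              x$observed_ratio, x$lower, x$upper))
  invisible(x)
}

#' Does a predicted ratio meet the Guest acceptance criterion?
#'
#' @param predicted_ratio Predicted GMR.
#' @param observed_ratio Observed GMR the bounds are built from.
#' @param delta Variability term.
#' @return Logical.
#' @export
guest_pass <- function(predicted_ratio, observed_ratio, delta = 1.25) {
  b <- guest_bounds(observed_ratio, delta)
  predicted_ratio >= b$lower && predicted_ratio <= b$upper
}

#' Intestinal P-gp sensitivity analysis
#'
#' Re-runs the scenario's representative subject (population medians,
#' deterministic) across a grid of victim intestinal P-gp RAF/REF values
#' and reports the victim AUC and Cmax ratios at each grid point (both
#' arms re-simulated per point, since baseline victim exposure also
#' depends on its P-gp activity).
#'
#' @param scenario A [ddi_scenario()].
#' @param raf_ref_grid Positive RAF/REF values.
#' @return Data.frame with `raf_ref`, `auc_ratio`, `cmax_ratio`.
#' @export
sensitivity_pgp <- function(scenario, raf_ref_grid) {
  if (!length(raf_ref_grid)) stop("empty RAF/REF grid")
  if (any(raf_ref_grid <= 0)) stop("RAF/REF values must be > 0")
  rows <- lapply(raf_ref_grid, function(rr) {
    sc <- scenario
    sc$victim$raf_ref <- rr
    arms <- simulate_arms(sc)
    data.frame(raf_ref = rr, auc_ratio = arms$auc_ratio,
               cmax_ratio = arms$cmax_ratio)
  })
  do.call(rbind, rows)
}
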