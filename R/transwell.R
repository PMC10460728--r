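#' Apparent permeability coefficient from transwell flux
#'
#' `P_app (cm/s) = (dQ/dt) / A / C0` with transport rate dQ/dt in dpm/s,
#' membrane area A in cm2 and initial donor concentration C0 in dpm/mL.
#'
#' @param dqdt Transport rate into the receiver compartment (dpm/s).
#' @param area Membrane area (cm2), > 0.
#' @param c0 Initial donor concentration (dpm/mL), > 0.
#' @return P_app in cm/s.
#' @examples
#' compute_papp(100, 1, 1e5) # 1e-3 cm/s
#' @export
compute_papp <- function(dqdt, area, c0) {
  if (any(area <= 0)) stop("area must be > 0")
  if (any(c0 <= 0)) stop("c0 must be > 0")
  dqdt / area / c0
}

#' Efflux ratios and percent-of-control from bidirectional P_app data
#'
#' Per additive concentration: `P_app ratio = P_app(B2A) / P_app(A2B)` in
#' each cell line, `corrected ratio = MDR1 ratio / control ratio`, and
#' `% of control = 100 * corrected / corrected(conc = 0)`.
#'
#' @param data A transwell data.frame (see [transwell_table()]) restricted
#'   to one additive, with all four `cell_line` x `direction` means per
#'   concentration.
#' @param additive Optional additive name used to subset `data`.
#' @param ratio_digits If non-`NULL`, round each P_app ratio and the
#'   corrected ratio to this many decimal places before the next step.
#'   `ratio_digits = 1` mirrors tabulated assay reports in which ratios are
#'   published to one decimal and downstream quantities are computed from
#'   the published values; the default (`NULL`) carries full precision.
#' @return A data.frame of class `efflux_summary` with columns
#'   `additive_conc`, `papp_ratio_control`, `papp_ratio_mdr1`,
#'   `corrected_ratio`, `pct_control`.
#' @export
summarize_efflux <- function(data, additive = NULL, ratio_digits = NULL) {
  if (!is.null(additive)) data <- data[data$additive == additive, ]
  validate_transwell_table(data)
  concs <- sort(unique(data$additive_conc_umol_L))
  if (!0 %in% concs)
    stop("missing zero-inhibitor row: cannot compute % of control")
  rnd <- function(x) if (is.null(ratio_digits)) x else round(x, ratio_digits)
  one <- function(conc, line) {
    d <- data[data$additive_conc_umol_L == conc & data$cell_line == line, ]
    a2b <- mean(d$papp_1e6_cm_s[d$direction == "A2B"])
    b2a <- mean(d$papp_1e6_cm_s[d$direction == "B2A"])
    if (!is.finite(a2b) || !is.finite(b2a))
      stop("each concentration needs all four cell_line x direction means")
    rnd(b2a / a2b)
  }
  ctl <- vapply(concs, one, numeric(1), line = "control")
  mdr <- vapply(concs, one, numeric(1), line = "MDR1")
  corrected <- rnd(mdr / ctl)
  out <- data.frame(additive_conc = concs,
                    papp_ratio_control = ctl,
                    papp_ratio_mdr1 = mdr,
                    corrected_ratio = corrected,
                    pct_control = 100 * corrected / corrected[concs == 0])
  class(out) <- c("efflux_summary", "data.frame")
  out
}

#' Hill inhibition model on the percent-of-control scale
#'
#' `% of control = 100 * (1 - i_max * I^C / (I^C + ic50^C))` where I is the
#' inhibitor concentration, `i_max` the maximal inhibitory effect (0-1),
#' and `C` the Hill factor.
#'
#' @param conc Inhibitor concentrations (umol/L).
#' @param i_max Maximal inhibition (0-1).
#' @param ic50 Half-maximal inhibitory concentration (umol/L).
#' @param hill_c Hill factor (> 0).
#' @return Predicted percent of control.
#' @export
pgp_inhibition_model <- function(conc, i_max, ic50, hill_c) {
  ic <- conc^hill_c
  100 * (1 - i_max * ic / (ic + ic50^hill_c))
}

#' Fit IC50 (and I_max, Hill factor) to percent-of-control data
#'
#' Unweighted least squares of the Hill inhibition model to
#' (concentration, % of control) pairs, all three parameters free, using a
#' fixed multi-start Levenberg-Marquardt search. The fitted IC50 is used
#' downstream as the competitive inhibition constant K_i (the substrate
#' probe concentration is far below its K_m, so IC50 ~ K_i).
#'
#' @param conc Inhibitor concentrations (umol/L), including the 0 baseline;
#'   at least four positive concentrations.
#' @param pct_control Percent of control at each concentration (100 at 0).
#' @return An object of class `inhibition_fit`: list with `ic50`, `i_max`,
#'   `hill_c`, `sse`, `converged`, `fitted`, `data`. When the series shows
#'   no inhibition (monotonically non-decreasing), `converged` is `FALSE`
#'   and `ic50` is `NA`.
#' @examples
#' eff <- summarize_efflux(transwell_table(), "enzalutamide", ratio_digits = 1)
#' fit_pgp_inhibition(eff$additive_conc, eff$pct_control)
#' @export
fit_pgp_inhibition <- function(conc, pct_control) {
  stopifnot(length(conc) == length(pct_control))
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (sum(conc > 0) < 4)
    stop("need >= 4 positive concentrations plus the 100% baseline")
  ord <- order(conc)
  if (all(diff(pct_control[ord]) >= 0)) {
    out <- list(ic50 = NA_real_, i_max = NA_real_, hill_c = NA_real_,
                sse = NA_real_, converged = FALSE, fitted = NULL,
                data = data.frame(conc, pct_control))
    class(out) <- "inhibition_fit"
    return(out)
  }
  obj <- function(p) pct_control - pgp_inhibition_model(conc, p[1], p[2], p[3])
  starts <- expand.grid(i_max = c(0.8, 1),
                        ic50 = 10^seq(-1.5, 1.5, length.out = 7),
                        hill_c = c(0.5, 1, 2))
  best <- multistart_lm(obj, starts,
                        lower = c(1e-3, 1e-9, 1e-3), upper = c(1, 1e9, 10))
  out <- list(ic50 = best$par[2], i_max = best$par[1], hill_c = best$par[3],
              sse = best$sse, converged = best$converged,
              fitted = pgp_inhibition_model(conc, best$par[1], best$par[2],
                                            best$par[3]),
              data = data.frame(conc, pct_control))
  class(out) <- "inhibition_fit"
  out
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("P-gp inhibition fit (Hill model on % of control):\n")
  cat(sprintf("  IC50 = %.4g umol/L   I_max = %.4g   Hill C = %.4g   SSE = %.4g   converged: %s\n",
              x$ic50, x$i_max, x$hill_c, x$sse, x$converged))
  invisible(x)
}
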