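#' Concentration-response model for enzyme induction
#'
#' Fold induction at inducer concentration `ct`:
#' `1 + (ind_max - 1) * ct / (ind_c50 + ct)`. A compound with no induction
#' potential has `ind_max = 1` (fold induction 1 at every concentration).
#'
#' @param ct Inducer concentration (umol/L), >= 0.
#' @param ind_max Maximal fold induction (>= 1).
#' @param ind_c50 Concentration giving half the maximal increase (umol/L).
#' @return Predicted fold induction (dimensionless).
#' @export
fold_induction_model <- function(ct, ind_max, ind_c50) {
  if (any(ct < 0)) stop("concentration must be >= 0")
  1 + (ind_max - 1) * ct / (ind_c50 + ct)
}

#' Fit Ind_max and IndC50 to fold-induction data
#'
#' Unweighted least squares of the induction concentration-response model
#' against mean fold increases, one compound x gene series at a time.
#' Optimization is a fixed multi-start Levenberg-Marquardt search
#' (log-spaced IndC50 starts crossed with a range of Ind_max starts), so
#' the fit is deterministic.
#'
#' @param concentration Inducer concentrations (umol/L), at least two
#'   distinct positive values.
#' @param fold_mean Mean fold increase over vehicle at each concentration.
#' @param exclude Optional concentrations to drop before fitting (e.g. the
#'   highest tested concentration where cytotoxicity depressed response).
#' @return An object of class `induction_fit`: list with `ind_max`,
#'   `ind_c50`, `sse`, `converged`, `fitted`, `data`.
#' @examples
#' fit_fold_induction(c(1, 10, 100), c(2.24, 6.90, 4.62))
#' @export
fit_fold_induction <- function(concentration, fold_mean, exclude = NULL) {
  stopifnot(length(concentration) == length(fold_mean))
  keep <- !(concentration %in% exclude)
  concentration <- concentration[keep]
  fold_mean <- fold_mean[keep]
  if (any(concentration < 0)) stop("concentration must be >= 0")
  if (any(fold_mean <= 0)) stop("fold_mean must be > 0")
  pos <- concentration > 0
  if (length(unique(concentration[pos])) < 2)
    stop("unidentifiable fit: need >= 2 distinct positive concentrations")

  if (all(fold_mean[pos] <= 1)) {
    out <- list(ind_max = 1, ind_c50 = NA_real_,
                sse = sum((fold_mean - 1)^2), converged = FALSE,
                fitted = rep(1, length(fold_mean)),
                data = data.frame(concentration, fold_mean))
    class(out) <- "induction_fit"
    return(out)
  }

  obj <- function(p)
    fold_mean - fold_induction_model(concentration, p[1], p[2])
  starts <- expand.grid(
    ind_max = c(1.5, max(fold_mean), 2 * max(fold_mean), 5, 10, 20),
    ind_c50 = 10^seq(-2, 2, length.out = 9))
  best <- multistart_lm(obj, starts,
                        lower = c(1, 1e-9), upper = c(1e6, 1e9))
  out <- list(ind_max = best$par[1], ind_c50 = best$par[2], sse = best$sse,
              converged = best$converged,
              fitted = fold_induction_model(concentration,
                                            best$par[1], best$par[2]),
              data = data.frame(concentration, fold_mean))
  class(out) <- "induction_fit"
  out
}

#' @export
print.induction_fit <- function(x, ...) {
  cat("Fold-induction fit (Emax on 1 + amplitude):\n")
  cat(sprintf("  Ind_max = %.4g   IndC50 = %.4g umol/L   SSE = %.4g   converged: %s\n",
              x$ind_max, x$ind_c50, x$sse, x$converged))
  invisible(x)
}

#' Calibrate in vitro Ind_max against a positive-control inducer
#'
#' Scales the in vitro induction amplitude (Ind_max - 1) by the ratio of
#' the positive control's accepted in vivo amplitude to its amplitude
#' observed in the same in vitro assay:
#' `1 + (ind_max_test - 1) * (ref_in_vivo - 1) / (pc_in_vitro - 1)`.
#' With rifampicin as positive control (in vitro CYP3A4 fold 8.05, in vivo
#' reference Ind_max 16) this maps enzalutamide's 5.9 to 11.43 and M2's
#' 5.1 to 9.72.
#'
#' @param ind_max_test In vitro Ind_max of the test compound (>= 1).
#' @param pc_in_vitro In vitro Ind_max of the positive control in the same
#'   assay (> 1).
#' @param ref_in_vivo Accepted in vivo Ind_max of the positive control
#'   (default 16, rifampicin on hepatic CYP3A4).
#' @return Calibrated Ind_max (fold).
#' @examples
#' calibrate_indmax(5.9, 8.05) # 11.43
#' @export
calibrate_indmax <- function(ind_max_test, pc_in_vitro, ref_in_vivo = 16) {
  if (any(c(ind_max_test, pc_in_vitro, ref_in_vivo) < 1))
    stop("all Ind_max values must be >= 1")
  if (pc_in_vitro == 1)
    stop("positive-control Ind_max of 1 carries no calibration information")
  1 + (ind_max_test - 1) * (ref_in_vivo - 1) / (pc_in_vitro - 1)
}

# Fixed multi-start Levenberg-Marquardt least squares; returns the start
# achieving the lowest SSE. Deterministic for a fixed start grid.
multistart_lm <- function(obj, starts, lower, upper) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = obj,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(par = unname(coef(fit)), sse = sse,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}
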