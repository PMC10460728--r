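# Brute-force least-squares oracles: dense grid search over the same
# objectives the optimizers minimize, kept independent of the fitting code.

grid_sse_induction <- function(conc, fold,
                               ind_max_grid = seq(1, 25, by = 0.02),
                               ind_c50_grid = 10^seq(-2, 2, length.out = 500)) {
  best <- Inf
  for (c50 in ind_c50_grid) {
    pred <- outer(conc / (c50 + conc), ind_max_grid - 1) + 1
    sse <- colSums((fold - pred)^2)
    best <- min(best, min(sse))
  }
  best
}

grid_sse_inhibition <- function(conc, pct,
                                i_max_grid = seq(0.5, 1, by = 0.005),
                                ic50_grid = 10^seq(-1.5, 1.5, length.out = 300),
                                hill_grid = seq(0.2, 3, by = 0.025)) {
  best <- Inf
  for (h in hill_grid) {
    ch <- conc^h
    for (ic in ic50_grid) {
      w <- ch / (ch + ic^h)
      pred <- 100 * (1 - outer(w, i_max_grid))
      sse <- colSums((pct - pred)^2)
      best <- min(best, min(sse))
    }
  }
  best
}

# a light-weight victim for fast engine/DDI property runs
quick_victim <- function(name = "probe", fm_cyp3a = 0.7, cl_h = 10,
                         fu = 0.2, bp = 1, vss = 0.5, ka = 1.2,
                         cl_r = 1, clint_pgp = 0, raf_ref = 1) {
  sys <- system_model()
  q <- sys$hepatic_blood_flow
  cl_b <- cl_h / bp
  clint_u <- q * cl_b / ((fu / bp) * (q - cl_b))
  per_mg <- clint_u * 1e6 / 60 / (sys$liver_mass * sys$mppgl)
  fm <- c(CYP3A4 = fm_cyp3a, other = 1 - fm_cyp3a)
  compound_model(name = name, mw = 400, fu = fu, bp = bp, vss = vss,
                 cl_r = cl_r, ka = ka, fa = 0.9,
                 clint_enzyme = per_mg * fm / sys$enzyme_abundance[names(fm)],
                 clint_pgp_in_vitro = clint_pgp, raf_ref = raf_ref)
}

# fabricate a one-compound sim_result from a concentration series, for
# exercising pk_metrics arithmetic directly
fake_result <- function(time, conc, name = "x") {
  st <- matrix(conc, ncol = 1, dimnames = list(NULL, paste0(name, ".cen")))
  structure(list(time = time, states = st,
                 pars = stats::setNames(list(list(vc = 1)), name),
                 spec = list(system = list(enterocyte_volume = 1))),
            class = "sim_result")
}
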