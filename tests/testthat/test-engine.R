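test_that("induction multiplier has the Emax limits", {
  expect_identical(induction_multiplier(0, 11.43, 1.5), 1)
  expect_equal(induction_multiplier(1.5, 11.43, 1.5), 1 + (11.43 - 1) / 2)
  expect_equal(induction_multiplier(1e9, 11.43, 1.5), 11.43, tolerance = 1e-6)
  expect_error(induction_multiplier(-1, 2, 1), ">= 0")
})

test_that("competitive inhibition scales activity as 1/(1 + I/Ki)", {
  expect_identical(inhibited_activity(10, 0, 1.67), 10)
  expect_equal(inhibited_activity(10, 1.67, 1.67), 5)
  acts <- inhibited_activity(10, c(0.1, 1, 10), 1.67)
  expect_true(all(diff(acts) < 0))
  expect_error(inhibited_activity(1, 1, 0), "ki")
})

test_that("pk metrics follow the trapezoid arithmetic", {
  t <- seq(0, 10, by = 0.1)
  const <- fake_result(t, rep(2, length(t)))
  m <- pk_metrics(const, "x", c(1, 7))
  expect_equal(m$auc, 2 * 6)
  expect_equal(m$cmax, 2)
  tri <- fake_result(t, pmax(0, 3 - abs(t - 5)))
  expect_equal(pk_metrics(tri, "x", c(0, 10))$tmax, 5)
  expect_error(pk_metrics(const, "x", c(5, 5)), "empty window")
  expect_error(pk_metrics(const, "x", c(0, 99)), "outside")
})

test_that("single-dose AUC matches the closed-form F*Dose/CL limit", {
  vic <- quick_victim(fm_cyp3a = 0, cl_h = 5, fu = 0.1, cl_r = 2)
  vic$fa <- 1 # no lumen loss: F = 1 - Eh exactly
  sp <- model_spec(compounds = list(vic))
  sim <- simulate_pbpk(sp, regimen("probe", 100), 600)
  m <- pk_metrics(sim, "probe", c(0, 600))
  q <- sp$system$hepatic_blood_flow
  pars <- enzddi:::build_engine_pars(sp)[["probe"]]
  clint <- sum(pars$clint_u)
  eh <- pars$fub * clint / (q + pars$fub * clint)
  cl_plasma <- eh * q * vic$bp + vic$cl_r
  auc_expected <- (1 - eh) * (100 * 1000 / vic$mw) / cl_plasma
  expect_equal(m$auc, auc_expected, tolerance = 1e-3)
})

test_that("dose-linearity: halving the dose halves AUC and Cmax", {
  vic <- quick_victim()
  sp <- model_spec(compounds = list(vic))
  hi <- pk_metrics(simulate_pbpk(sp, regimen("probe", 100), 240),
                   "probe", c(0, 240))
  lo <- pk_metrics(simulate_pbpk(sp, regimen("probe", 50), 240),
                   "probe", c(0, 240))
  expect_equal(hi$auc / lo$auc, 2, tolerance = 1e-6)
  expect_equal(hi$cmax / lo$cmax, 2, tolerance = 1e-6)
})

test_that("clamped inducer drives the enzyme pool to the Emax multiplier
           with half-life ln2/kdeg", {
  enz <- enzalutamide_model()
  sp <- model_spec(compounds = list(enz), perpetrators = "enzalutamide")
  cu <- enz$indc50                       # half-maximal unbound exposure
  cc <- cu / enz$fu
  sim <- simulate_pbpk(sp, regimen("enzalutamide", 1e-6, start = 0), 700,
                       solver_opts = list(clamp = c(enzalutamide = cc)))
  mult <- induction_multiplier(cu, enz$indmax_calibrated, enz$indc50)
  pool <- enzyme_series(sim, "liver")
  expect_equal(pool[length(pool)], mult, tolerance = 1e-3,
               ignore_attr = TRUE)
  kdeg <- sp$system$kdeg[["liver"]]
  t_half <- log(2) / kdeg
  pool_at_half <- stats::approx(sim$time, pool, t_half)$y
  expect_equal(pool_at_half, (mult + 1) / 2, tolerance = 1e-3)
})

test_that("enzyme pools return to baseline after perpetrator washout", {
  sp <- model_spec(compounds = list(enzalutamide_model()),
                   perpetrators = "enzalutamide")
  sim <- simulate_pbpk(sp, regimen("enzalutamide", 160), 1560,
                       solver_opts = list(dt = 0.5))
  n <- length(sim$time)
  expect_gt(max(enzyme_series(sim, "liver")), 1.05) # induction happened
  expect_equal(enzyme_series(sim, "liver")[n], 1, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(enzyme_series(sim, "gut")[n], 1, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("mass balance closes for a full interaction simulation", {
  vic <- victim_model("digoxin")
  sp <- model_spec(compounds = list(enzalutamide_model(), m2_model(), vic),
                   perpetrators = c("enzalutamide", "M2"),
                   metabolite_links = list(list(parent = "enzalutamide",
                                                metabolite = "M2")))
  sim <- simulate_pbpk(sp, list(regimen("enzalutamide", 160, 24, 10),
                                regimen("digoxin", 0.25, start = 216)),
                       264, solver_opts = list(dt = 0.25))
  mb <- mass_balance(sim)
  expect_true(all(abs(mb$rel_error) < 1e-6))
})

test_that("victim exposure responds monotonically to Ind_max and Ki", {
  base_auc <- function(indmax, ki) {
    enz <- enzalutamide_model()
    enz$indmax_calibrated <- indmax
    enz$ki_cyp3a <- ki
    vic <- quick_victim(fm_cyp3a = 0.9, cl_h = 20, fu = 0.05)
    sp <- model_spec(compounds = list(enz, vic),
                     perpetrators = "enzalutamide")
    sim <- simulate_pbpk(sp, list(regimen("enzalutamide", 160, 24, 8),
                                  regimen("probe", 10, start = 144)),
                         192, solver_opts = list(dt = 0.25))
    pk_metrics(sim, "probe", c(144, 192))$auc
  }
  aucs_ind <- vapply(c(1, 6, 11.43), base_auc, numeric(1), ki = 42)
  expect_true(all(diff(aucs_ind) < 0))
  # weaker CYP3A inhibition (larger Ki) exposes more victim clearance
  aucs_ki <- vapply(c(5, 42, 500), base_auc, numeric(1), indmax = 11.43)
  expect_true(all(diff(aucs_ki) < 0))
})

test_that("tightening solver tolerances leaves AUC unchanged to 0.01%", {
  vic <- victim_model("midazolam")
  sp <- model_spec(compounds = list(vic))
  m1 <- pk_metrics(simulate_pbpk(sp, regimen("midazolam", 2), 48),
                   "midazolam", c(0, 48))
  m2 <- pk_metrics(simulate_pbpk(sp, regimen("midazolam", 2), 48,
                                 solver_opts = list(atol = 1e-11,
                                                    rtol = 1e-9)),
                   "midazolam", c(0, 48))
  expect_equal(m1$auc, m2$auc, tolerance = 1e-4)
})

test_that("simulation input validation catches bad regimens", {
  sp <- model_spec(compounds = list(quick_victim()))
  expect_error(simulate_pbpk(sp, regimen("ghost", 10), 24), "unknown compound")
  expect_error(simulate_pbpk(sp, regimen("probe", 10, 24, 5), 24),
               "does not cover")
})
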