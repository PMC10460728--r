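test_that("induction generator is seed-deterministic and schema-valid", {
  a <- gen_induction_dataset(5.9, 1.5, seed = 123)
  b <- gen_induction_dataset(5.9, 1.5, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a$data$fold_mean,
                         gen_induction_dataset(5.9, 1.5, seed = 124)$data$fold_mean))
  # same schema as the packaged assay table
  expect_silent(enzddi:::validate_induction_table(a$data))
  expect_identical(a$truth$seed, 123)
})

test_that("noise-free induction data lie exactly on the Emax curve", {
  d <- gen_induction_dataset(4, 2, lot_cv = 0, seed = 5)
  expect_equal(d$data$fold_mean,
               fold_induction_model(d$data$concentration_umol_L, 4, 2))
  fit <- fit_fold_induction(d$data$concentration_umol_L, d$data$fold_mean)
  expect_equal(fit$ind_max, 4, tolerance = 1e-4)
})

test_that("transwell generator round-trips through the fitting pipeline", {
  g <- gen_transwell_dataset(ic50 = 1.67, i_max = 1, hill_c = 0.8,
                             noise_cv = 0, seed = 9)
  expect_silent(enzddi:::validate_transwell_table(g$data))
  eff <- summarize_efflux(g$data)
  fit <- fit_pgp_inhibition(eff$additive_conc, eff$pct_control)
  expect_equal(fit$ic50, 1.67, tolerance = 1e-4)
  expect_equal(fit$hill_c, 0.8, tolerance = 1e-4)
  # control monolayers have no directional asymmetry
  expect_equal(eff$papp_ratio_control, rep(1, nrow(eff)))
})

test_that("a non-inhibitor generates a flat percent-of-control profile", {
  g <- gen_transwell_dataset(ic50 = 1, i_max = 0, hill_c = 1,
                             noise_cv = 0, seed = 2)
  eff <- summarize_efflux(g$data)
  expect_equal(eff$pct_control, rep(100, nrow(eff)))
})

test_that("generated victims are valid, seeded compounds", {
  v1 <- gen_victim_compound(seed = 31)
  v2 <- gen_victim_compound(seed = 31)
  expect_identical(v1, v2)
  expect_s3_class(v1, "compound_model")
  expect_true(attr(v1, "truth")$fm_cyp3a >= 0)
})

test_that("induction isolates to the CYP3A pathway for fm_CYP3A = 0 victims", {
  vic <- gen_victim_compound(seed = 3, fm_cyp3a = 0)
  vic$clint_pgp_in_vitro <- 0 # no P-gp route either
  sc <- ddi_scenario(vic, victim_dose = 10, pretreat_days = 3, window = 24,
                     n_subjects = 1,
                     switches = list(pgp_inhibition = FALSE,
                                     oat3_inhibition = FALSE),
                     solver_opts = list(atol = 1e-12, rtol = 1e-10))
  res <- run_ddi(sc)
  expect_equal(res$auc_ratio_gmr, 1, tolerance = 1e-6)
})

test_that("victims with larger CYP3A fractions see stronger induction", {
  ratio_for <- function(fm) {
    vic <- quick_victim(fm_cyp3a = fm, cl_h = 12, fu = 0.1)
    sc <- ddi_scenario(vic, victim_dose = 10, pretreat_days = 4, window = 24,
                       n_subjects = 1, solver_opts = list(dt = 0.25))
    run_ddi(sc)$auc_ratio_gmr
  }
  expect_lt(ratio_for(0.8), ratio_for(0.2))
})
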