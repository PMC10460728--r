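test_that("Guest acceptance intervals reproduce the published criteria", {
  b <- guest_bounds(1.29)
  expect_equal(round(c(b$lower, b$upper), 2), c(0.91, 1.83))
  b <- guest_bounds(1.17)
  expect_equal(round(c(b$lower, b$upper), 2), c(0.86, 1.59))
  b <- guest_bounds(0.14)
  expect_equal(round(c(b$lower, b$upper), 2), c(0.07, 0.27))
  b <- guest_bounds(0.23)
  expect_equal(round(c(b$lower, b$upper), 2), c(0.13, 0.42))
  # at R = 1 the limit collapses to the classical bioequivalence band
  b <- guest_bounds(1)
  expect_equal(c(b$lower, b$upper), c(0.8, 1.25))
  expect_error(guest_bounds(0), "> 0")
})

test_that("Guest bounds have exact reciprocal symmetry", {
  for (r in c(0.1, 0.37, 0.9, 1.5, 4.2)) {
    a <- guest_bounds(r)
    b <- guest_bounds(1 / r)
    expect_equal(b$lower, 1 / a$upper)
    expect_equal(b$upper, 1 / a$lower)
  }
  expect_true(guest_pass(1.30, 1.29))
  expect_false(guest_pass(2.00, 1.29))
})

test_that("geometric mean ratio summaries follow the log-scale t interval", {
  expect_equal(unname(gmr_ci(rep(1.7, 5))), rep(1.7, 3))
  expect_equal(gmr_ci(c(2.3, 1 / 2.3))[["gmr"]], 1)
  expect_error(gmr_ci(c(1, -2)), "positive")
  # bootstrap oracle on a fixed sample
  set.seed(7)
  x <- exp(rnorm(40, mean = log(0.7), sd = 0.25))
  g <- gmr_ci(x)
  set.seed(8)
  boot <- replicate(4000, exp(mean(log(sample(x, replace = TRUE)))))
  expect_equal(g[["gmr"]], exp(mean(log(x))))
  expect_equal(g[["lower"]], unname(quantile(boot, 0.05)), tolerance = 0.02)
  expect_equal(g[["upper"]], unname(quantile(boot, 0.95)), tolerance = 0.02)
})

test_that("population DDI runs are seed-reproducible", {
  vic <- quick_victim(fm_cyp3a = 0.8, cl_h = 15, fu = 0.1)
  sc <- ddi_scenario(vic, victim_dose = 10, pretreat_days = 2, window = 24,
                     n_subjects = 3, seed = 11,
                     solver_opts = list(dt = 0.25))
  r1 <- run_ddi(sc)
  r2 <- run_ddi(sc)
  expect_identical(r1$per_subject, r2$per_subject)
  expect_lt(r1$auc_ratio_gmr, 1)  # induction dominates for this victim
  expect_true(r1$ci90_auc[[1]] <= r1$auc_ratio_gmr &&
                r1$auc_ratio_gmr <= r1$ci90_auc[[2]])
})

test_that("with all interaction switches off the exposure ratio is unity", {
  vic <- quick_victim(fm_cyp3a = 0.8, cl_h = 15, fu = 0.1, clint_pgp = 50)
  sc <- ddi_scenario(vic, victim_dose = 10, pretreat_days = 2, window = 24,
                     n_subjects = 1,
                     switches = list(cyp3a_induction = FALSE,
                                     cyp3a_inhibition = FALSE,
                                     pgp_inhibition = FALSE,
                                     oat3_inhibition = FALSE),
                     solver_opts = list(atol = 1e-12, rtol = 1e-10))
  res <- run_ddi(sc)
  expect_equal(res$auc_ratio_gmr, 1, tolerance = 1e-9)
  expect_equal(res$cmax_ratio_gmr, 1, tolerance = 1e-9)
})

test_that("between-subject variability widens the interval, not the center", {
  vic <- quick_victim(fm_cyp3a = 0.8, cl_h = 15, fu = 0.1)
  base <- ddi_scenario(vic, victim_dose = 10, pretreat_days = 2,
                       window = 24, n_subjects = 1,
                       solver_opts = list(dt = 0.25))
  det <- run_ddi(base)
  pop <- base
  pop$n_subjects <- 6
  popr <- run_ddi(pop)
  expect_gt(popr$ci90_auc[[2]] - popr$ci90_auc[[1]], 0)
  expect_equal(popr$auc_ratio_gmr, det$auc_ratio_gmr, tolerance = 0.15)
})

test_that("sensitivity grids validate their input", {
  sc <- ddi_scenario("apixaban", n_subjects = 1)
  expect_error(sensitivity_pgp(sc, numeric()), "empty")
  expect_error(sensitivity_pgp(sc, c(1, -1)), "> 0")
})
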