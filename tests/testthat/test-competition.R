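test_that("cheng_prusoff degenerates to the IC50 at zero radioligand", {
  expect_equal(cheng_prusoff(2e-9, 0, 1e-9), 2e-9)
  # IC50 = 2 nM, KD = 1 nM, [D] = 1 nM -> KI = 1 nM (pKI 9)
  expect_equal(-log10(cheng_prusoff(2e-9, 1e-9, 1e-9)), 9)
  # monotonicity: KI < IC50 whenever [D] > 0
  set.seed(13)
  ic <- 10^runif(20, -9, -5); kd <- 10^runif(20, -10, -8)
  expect_true(all(cheng_prusoff(ic, 1e-9, kd) < ic))
})

test_that("one-site data are fitted as one site with correct pKI", {
  cfg <- sim_config(seed = 19, cv_binding = 0)
  sim <- simulate_competition(cfg, pKI = 4.62, radioligand_pKD = 9.6)
  f <- fit_competition(sim, 1e-9, 9.6)
  expect_identical(f$model, "one_site")
  expect_equal(f$pKI_low, 4.62, tolerance = 1e-5)
  # and the Cheng-Prusoff relation holds against the raw pIC50
  expect_equal(f$pKI_low, f$pIC50_low + log10(1 + 1e-9 / 10^-9.6),
               tolerance = 1e-10)
})

test_that("biphasic data select the two-site model and recover both sites", {
  cfg <- sim_config(seed = 29)
  sim <- simulate_competition(cfg, "iperoxo", pKI = c(8.35, 6.20),
                              f_low = 50, radioligand_pKD = 9.6)
  f <- fit_competition(sim, 1e-9, 9.6)
  expect_identical(f$model, "two_site")
  expect_lt(f$p_value, 0.05)
  expect_equal(f$pKI_high, 8.35, tolerance = 0.15)
  expect_equal(f$pKI_low, 6.20, tolerance = 0.15)
  expect_equal(f$f_low, 50, tolerance = 10)
  expect_gt(f$pIC50_high, f$pIC50_low)
  # the simulated displacement curve is visibly biphasic: inflections
  # bracket the two pIC50s
  ymean <- rowMeans(sim$responses)
  mid_lo <- min(sim$concentrations[ymean < 75])
  mid_hi <- min(sim$concentrations[ymean < 25])
  expect_lt(-log10(mid_hi), attr(sim, "truth")$pIC50[2] + 1)
  expect_gt(-log10(mid_lo), attr(sim, "truth")$pIC50[1] - 1)
})

test_that("two-site fit collapses to one site at boundary fractions", {
  # data generated with f_low near 0 or 100 are effectively one-site; the
  # F-test must not prefer the two-site model
  for (f_low in c(1, 99)) {
    cfg <- sim_config(seed = 37 + f_low, cv_binding = 0)
    sim <- simulate_competition(cfg, pKI = c(8.0, 6.0), f_low = f_low,
                                radioligand_pKD = 9.6)
    fit <- fit_competition(sim, 1e-9, 9.6)
    one_equiv <- if (f_low == 1) 8.0 else 6.0
    pk <- if (fit$model == "one_site") fit$pKI_low else
      if (f_low == 1) fit$pKI_high else fit$pKI_low
    expect_equal(pk, one_equiv, tolerance = 0.05)
  }
})

test_that("an incompletely displacing competitor triggers a warning", {
  x <- 10^seq(-9, -4, by = 0.5)
  y <- 40 + 60 * (1 - x / (x + 1e-7))  # bottom plateau 40%
  s <- conc_response_series(x, matrix(rep(y, 4), ncol = 4),
                            pathway = "binding",
                            response_unit = "pct_of_control")
  expect_warning(fit_competition(s, 1e-9, 9.6), "incomplete inhibition")
})

test_that("the two-site F-test holds its nominal type-I error rate", {
  # one-site truth; selection of two_site should occur at ~ alpha = 0.05
  n_sim <- 400
  picks <- 0L
  for (i in seq_len(n_sim)) {
    cfg <- sim_config(seed = 9000 + i)
    sim <- simulate_competition(cfg, pKI = 5.0, radioligand_pKD = 9.6)
    f <- fit_competition(sim, 1e-9, 9.6)
    if (f$model == "two_site") picks <- picks + 1L
  }
  rate <- picks / n_sim
  # binomial tolerance around 0.05 at n = 400 (3 SE)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})
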