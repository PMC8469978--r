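test_that("the seed fully determines simulator output", {
  a <- simulate_functional(sim_config(seed = 4), "carbachol", 30.7, 1.41, 6.6)
  b <- simulate_functional(sim_config(seed = 4), "carbachol", 30.7, 1.41, 6.6)
  c <- simulate_functional(sim_config(seed = 5), "carbachol", 30.7, 1.41, 6.6)
  expect_identical(a[[1]]$responses, b[[1]]$responses)
  expect_false(identical(a[[1]]$responses, c[[1]]$responses))
  # different seeds share identical ground-truth metadata
  expect_identical(attr(a, "truth"), attr(c, "truth"))

  s1 <- simulate_saturation(sim_config(seed = 8))
  s2 <- simulate_saturation(sim_config(seed = 8))
  expect_identical(s1$total_dpm, s2$total_dpm)
})

test_that("saturation simulation matches the quadruplicate 6-point design", {
  sim <- simulate_saturation(sim_config(seed = 2))
  expect_equal(length(sim$added_conc), 6)
  expect_equal(range(sim$added_conc), c(63e-12, 2000e-12))
  expect_equal(dim(sim$total_dpm), c(6, 4))
  expect_equal(dim(sim$nonspecific_dpm), c(6, 4))
  # CV = 0 puts points exactly on isotherm + linear nonspecific component
  sim0 <- simulate_saturation(sim_config(seed = 2, cv_binding = 0))
  truth <- attr(sim0, "truth")
  expected <- opbias:::molar_to_dpm(truth$bound + truth$nonspecific,
                                    sim0$specific_activity, sim0$volume_L)
  expect_equal(sim0$total_dpm[, 1], expected, tolerance = 1e-12)
  ns_exp <- opbias:::molar_to_dpm(0.005 * sim0$added_conc,
                                  sim0$specific_activity, sim0$volume_L)
  expect_equal(sim0$nonspecific_dpm[, 1], ns_exp, tolerance = 1e-12)
})

test_that("replicate means converge to the model value (law of large numbers)", {
  cfg <- sim_config(seed = 12, n_replicates_binding = 10000)
  sim <- simulate_saturation(cfg)
  truth <- attr(sim, "truth")
  expected <- opbias:::molar_to_dpm(truth$bound + truth$nonspecific,
                                    sim$specific_activity, sim$volume_L)
  rel <- abs(rowMeans(sim$total_dpm) - expected) / expected
  expect_true(all(rel < 0.002))
})

test_that("competition simulation spans 100% to full displacement", {
  sim <- simulate_competition(sim_config(seed = 14, cv_binding = 0),
                              pKI = 5.0)
  y <- sim$responses[, 1]
  expect_equal(max(y), 100, tolerance = 1)      # no competitor limit
  expect_equal(min(y), 0, tolerance = 1)        # complete inhibition
  # zero competitor concentration gives exactly 100% of control
  x0 <- 1e-15
  truth <- attr(sim, "truth")
  expect_equal(100 - 100 * x0 / (x0 + 10^-truth$pIC50), 100, tolerance = 1e-3)
})

test_that("functional simulation obeys the basal and noise conventions", {
  cfg <- sim_config(seed = 21)
  sims <- simulate_functional(cfg, "carbachol", 30.7, 1.41, 6.6)
  expect_length(sims, 3)
  for (s in sims) {
    expect_equal(dim(s$responses)[2], 3)   # triplicate
    expect_equal(length(s$concentrations), 9)
    # basal draw within the 2-3% band of incorporated counts
    b <- attr(s, "basal_dpm") / cfg$incorporated_dpm
    expect_gte(b, 0.02); expect_lte(b, 0.03)
  }
  # noise-free curve hits the rebased plateau and potency exactly
  sims0 <- simulate_functional(sim_config(seed = 21, cv_functional = 0),
                               "carbachol", 30.7, 1.41, 6.6)
  y <- sims0[[1]]$responses[, 1]
  x <- sims0[[1]]$concentrations
  expect_equal(max(y), operational_response(max(x), 30.7, 1.41, 6.6),
               tolerance = 1e-9)
  # rebased plateau: 1 + (EMAX - 1) * tau / (tau + 1)
  expect_equal(operational_response(1, 30.7, 1.41, 6.6),
               1 + 29.7 * 1.41 / 2.41, tolerance = 1e-6)
  h <- fit_hill(sims0[[1]])
  expect_equal(h$pEC50, 6.6 + log10(2.41), tolerance = 1e-6)
  # "no response" truth: flat at 1 plus noise
  fl <- simulate_functional(cfg, "JR6", tau = 0)
  expect_equal(mean(fl[[1]]$responses), 1, tolerance = 0.05)
  expect_equal(attr(fl, "truth")$tau, 0)
})

test_that("cAMP simulation is biphasic at wt and flat at fused constructs", {
  cfg0 <- sim_config(seed = 33, cv_functional = 0, n_experiments = 1)
  wt <- simulate_camp(cfg0, "wt", pIC50 = 7, pEC50 = 5)[[1]]
  ym <- rowMeans(wt$responses)
  # minimum of the mean curve lies between the two component midpoints
  xmin <- wt$concentrations[which.min(ym)]
  expect_gt(xmin, 10^-7); expect_lt(xmin, 10^-5)
  # inhibitory amplitude 0 switches off the descending limb: pure Hill rise
  stim <- simulate_camp(cfg0, "wt", inhib_amplitude = 0)[[1]]
  expect_true(all(diff(rowMeans(stim$responses)) >= -1e-12))
  # fused construct: flat, and the flat test says no coupling
  fused <- simulate_camp(sim_config(seed = 34, n_experiments = 1),
                         "fused")[[1]]
  expect_identical(flat_test(fused)$verdict, "no coupling")
})
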