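test_that("fit_operational recovers noise-free parameters exactly", {
  s <- op_series(2.8, 7.64, 30.7)
  f <- fit_operational(s, 30.7)
  expect_equal(f$tau, 2.8, tolerance = 1e-6)
  expect_equal(f$pKA, 7.64, tolerance = 1e-6)
  expect_false(f$no_response)
})

test_that("two-step fit equals the closed-form transform on noise-free data", {
  set.seed(11)
  for (i in 1:8) {
    tau <- 10^runif(1, -0.5, 0.9); pKA <- runif(1, 5.5, 8.5)
    s <- op_series(tau, pKA, 27.1)
    f <- fit_operational(s, 27.1)
    cf <- hill_to_operational(fit_hill(s), 27.1)
    expect_equal(f$tau, cf$tau, tolerance = 1e-6)
    expect_equal(f$pKA, cf$pKA, tolerance = 1e-6)
  }
})

test_that("flat series yield tau = 0 with pKA not calculated", {
  sims <- simulate_functional(sim_config(seed = 17), "JR6", tau = 0)
  f <- fit_operational(sims, 30.7)
  expect_equal(f$tau, 0)
  expect_true(is.na(f$pKA))
})

test_that("operational fits over replicate experiments recover tau with scatter", {
  sims <- simulate_functional(sim_config(seed = 23), "oxotremorine",
                              30.7, 2.8, 7.64)
  f <- fit_operational(sims, 30.7)
  expect_equal(f$n_experiments, 3)
  expect_lt(abs(f$tau - 2.8) / 2.8, 0.1)
  expect_gt(f$tau_sd, 0)
})

test_that("tau is invariant to joint rescaling of concentrations and KA", {
  s1 <- op_series(1.5, 7, 27.1)
  s2 <- conc_response_series(s1$concentrations * 1000, s1$responses)
  f1 <- fit_operational(s1, 27.1)
  f2 <- fit_operational(s2, 27.1)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-6)
  expect_equal(f2$pKA, f1$pKA - 3, tolerance = 1e-6)
})

test_that("raising tau at fixed KA raises fitted E'MAX and pEC50", {
  taus <- c(0.5, 1, 2, 4, 8)
  hs <- lapply(taus, function(t) fit_hill(op_series(t, 7, 30.7)))
  em <- vapply(hs, function(h) h$emax_prime, numeric(1))
  pe <- vapply(hs, function(h) h$pEC50, numeric(1))
  expect_true(all(diff(em) > 0))
  expect_true(all(diff(pe) > 0))
})

test_that("system EMAX fit refuses degenerate inputs", {
  s <- op_series(1.41, 6.6, 30.7, ligand = "carbachol")
  # single curve: likelihood is flat along EMAX*tau/(tau+1) = const
  expect_error(fit_system_emax(s), "ridge")
  # equi-efficacious standards
  s2 <- op_series(1.41, 7.4, 30.7, ligand = "other")
  expect_error(fit_system_emax(list(s, s2)), "not identifiable")
})

test_that("the EMAX ridge is numerically flat above the largest plateau", {
  # profiled SSE does not increase as the ceiling grows: direct numerical
  # demonstration that EMAX is identified only as a lower bound
  pan <- list(op_series(1.41, 6.6, 30.7, ligand = "carbachol"),
              op_series(2.799, 7.64, 30.7, ligand = "oxotremorine"),
              op_series(0.946, 6.39, 30.7, ligand = "pilocarpine"))
  fit <- fit_system_emax(pan)
  expect_true(fit$ridge)
  prof <- fit$profile
  expect_true(all(diff(prof$sse) <= 1e-6 * (1 + prof$sse[-nrow(prof)])))
  # the edge is a lower bound for the generating ceiling
  expect_lte(fit$system_emax, 30.7)
  # and cannot be below the largest apparent maximum
  emx <- max(vapply(pan, function(s) fit_hill(s)$emax_prime, numeric(1)))
  expect_gte(fit$system_emax, emx)
})

test_that("a full agonist pins the EMAX edge at its own plateau", {
  pan <- list(op_series(1.41, 6.6, 30.7, ligand = "carbachol"),
              op_series(1e6, 7.6, 30.7, ligand = "iperoxo", span = 3))
  fit <- fit_system_emax(pan)
  expect_equal(fit$system_emax, 30.7, tolerance = 0.01)
})

test_that("bias quantities are invariant to the adopted ceiling (ridge)", {
  pan <- list(op_series(1.41, 6.6, 30.7, ligand = "carbachol"),
              op_series(2.799, 7.64, 30.7, ligand = "oxotremorine"),
              op_series(0.946, 6.39, 30.7, ligand = "pilocarpine"))
  dlog <- function(emax) {
    fits <- lapply(pan, fit_operational, system_emax = emax)
    q <- vapply(fits, function(f) log10(f$tau) + f$pKA, numeric(1))
    q - q[1]
  }
  expect_equal(dlog(30.7), dlog(45), tolerance = 1e-5)
  expect_equal(dlog(30.7), dlog(26), tolerance = 1e-5)
})
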