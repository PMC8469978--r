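test_that("hill_response evaluates the fold-over-basal Hill equation", {
  # midpoint at EC50: (1 + E'max)/2
  expect_equal(hill_response(10^-6.5, 6.5, 18, 1), 9.5)
  # basal at zero concentration
  expect_equal(hill_response(0, 7, 25, 2), 1)
  # frozen value from independent arithmetic:
  # 1 + 17 * 1e-5 / (10^-6.99 + 1e-5)
  expect_equal(hill_response(1e-5, 6.99, 18, 1), 17.8278, tolerance = 1e-4)
  expect_error(hill_response(-1e-9, 7, 18, 1), "non-negative")
  expect_error(hill_response(1e-9, 7, 18, 0), "positive")
})

test_that("hill_response is monotone non-decreasing in concentration", {
  set.seed(101)
  for (i in 1:25) {
    pec <- runif(1, 4, 10); em <- runif(1, 1.1, 40); nh <- runif(1, 0.3, 4)
    x <- sort(10^runif(50, -12, -2))
    y <- hill_response(x, pec, em, nh)
    expect_true(all(diff(y) >= -1e-12))
    expect_lte(max(y), em * (1 + 1e-12))  # asymptote
  }
})

test_that("operational_response honours plateau and potency identities", {
  # apparent maximum of the plain variant = EMAX*tau/(tau+1)
  ymax <- operational_response(1, 30.7, 1.41, 6.6, variant = "plain")
  expect_equal(ymax, 30.7 * 1.41 / 2.41, tolerance = 1e-4)
  expect_equal(ymax, 17.96, tolerance = 1e-3)
  # half-max concentration at pEC50 = pKA + log10(1 + tau)
  pec50 <- 7.64 + log10(1 + 2.8)
  at_half <- operational_response(10^-pec50, 30.7, 2.8, 7.64)
  plateau <- operational_response(1, 30.7, 2.8, 7.64)
  expect_equal(at_half, (1 + plateau) / 2, tolerance = 1e-6)
  # full-agonist limit: plateau -> system EMAX
  expect_equal(operational_response(1e-2, 30.7, 1e9, 7), 30.7,
               tolerance = 1e-6)
  # rebased variant anchors basal at 1
  expect_equal(operational_response(0, 30.7, 2.8, 7.64), 1)
  expect_error(operational_response(1e-7, 30.7, 0, 7.64), "tau")
})

test_that("hill_to_operational implements the closed-form inversion", {
  # plain-ceiling variant reproduces the published tau for carbachol at the
  # M2 fusion: 18 / (30.7 - 18)
  op <- hill_to_operational(list(pEC50 = 6.99, emax_prime = 18), 30.7,
                            variant = "plain")
  expect_equal(op$tau, 18 / 12.7, tolerance = 1e-12)
  expect_equal(op$tau, 1.417, tolerance = 1e-3)
  # pKA = pEC50 - log10(1 + tau) for oxotremorine at the M2 fusion
  op2 <- hill_to_operational(list(pEC50 = 8.22, emax_prime = 22.4), 30.7,
                             variant = "plain")
  expect_equal(op2$pKA, 8.22 - log10(1 + op2$tau), tolerance = 1e-12)
  # half-ceiling gives tau = 1 exactly under the plain variant
  op3 <- hill_to_operational(list(pEC50 = 7, emax_prime = 15.35), 30.7,
                             variant = "plain")
  expect_equal(op3$tau, 1)
  expect_error(
    hill_to_operational(list(pEC50 = 7, emax_prime = 31), 30.7),
    "not identifiable")
  expect_error(
    hill_to_operational(list(pEC50 = 7, emax_prime = 10, nH = 1.5), 30.7),
    "nH")
})

test_that("operational <-> Hill round trips are exact on noise-free grids", {
  set.seed(202)
  for (i in 1:15) {
    tau <- 10^runif(1, -0.7, 1); pKA <- runif(1, 5, 9)
    emax <- runif(1, 15, 40)
    s <- op_series(tau, pKA, emax, span = 2.5)
    h <- fit_hill(s)
    # refit with the Hill model returns pEC50 = pKA + log10(1 + tau)
    expect_equal(h$pEC50, pKA + log10(1 + tau), tolerance = 1e-6)
    expect_equal(h$nH, 1, tolerance = 1e-5)
    # closed-form back-transform then forward evaluation reproduces curve
    op <- hill_to_operational(h, emax)
    y1 <- operational_response(s$concentrations, emax, op$tau, op$pKA)
    y0 <- s$responses[, 1]
    expect_equal(y1, y0, tolerance = 1e-9)
  }
})
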