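test_that("compute_RAi is 1 for the reference and table-oriented", {
  p <- data.frame(ligand = c("carbachol", "oxotremorine"),
                  tau = c(1.41, 2.799), pKA = c(6.6, 7.64))
  b <- compute_RAi(p, method = "tau_ka")
  expect_equal(b$RAi[b$ligand == "carbachol"], 1)
  # a more potent + efficacious agonist gives RAi > 1 (table orientation)
  expect_gt(b$RAi[b$ligand == "oxotremorine"], 1)
  expect_error(compute_RAi(p, reference = "iperoxo"), "not found")
})

test_that("RAi reproduces published values from tabulated parameters", {
  # oxotremorine vs carbachol at the M2 fusion via E'MAX/EC50 (printed 21.4)
  tab <- ref_variant_params()
  m2 <- tab[tab$construct == "M2_Ga16", ]
  b <- compute_RAi(m2, method = "emax_ec50")
  expect_equal(b$RAi[b$ligand == "oxotremorine"], 21.4, tolerance = 0.05)
  # iperoxo vs carbachol at wild-type M5 via tau/KA (printed 912)
  m5 <- tab[tab$construct == "M5_wt", ]
  b5 <- compute_RAi(m5, method = "tau_ka")
  expect_equal(b5$RAi[b5$ligand == "iperoxo"], 912, tolerance = 0.05)
  # non-responding agonists get RAi = 0
  f <- ref_fused_params()
  bm2 <- compute_RAi(f[f$receptor == "M2", ], method = "tau_ka")
  expect_equal(bm2$RAi[bm2$ligand %in% c("JR6", "JR7")], c(0, 0))
})

test_that("RAi via tau/KA and via E'MAX/EC50 agree on noise-free data", {
  # algebraic identity through the plain-ceiling closed-form transform when
  # nH = 1: tau/KA = E'MAX / (EMAX * EC50), so the EMAX factor cancels in
  # the ratio and both routes coincide
  set.seed(55)
  emax <- 27.1
  taus <- c(0.887, 10^runif(3, -0.5, 0.8))
  pkas <- c(6.8, runif(3, 5.5, 8.5))
  ligs <- c("carbachol", paste0("L", 1:3))
  hills <- mapply(function(t, k, l) fit_hill(op_series(t, k, emax, ligand = l)),
                  taus, pkas, ligs, SIMPLIFY = FALSE)
  ops <- lapply(hills, hill_to_operational, system_emax = emax,
                variant = "plain")
  p1 <- data.frame(ligand = ligs,
                   tau = vapply(ops, function(o) o$tau, 1),
                   pKA = vapply(ops, function(o) o$pKA, 1))
  p2 <- data.frame(ligand = ligs,
                   emax_prime = vapply(hills, function(h) h$emax_prime, 1),
                   pEC50 = vapply(hills, function(h) h$pEC50, 1))
  r1 <- compute_RAi(p1, method = "tau_ka")$RAi
  r2 <- compute_RAi(p2, method = "emax_ec50")$RAi
  expect_equal(r1, r2, tolerance = 1e-9)
  # orientation consistency: RAi > 1 iff log(tau/KA) exceeds the reference's
  b <- compute_RAi(p1, method = "tau_ka")
  expect_equal(b$RAi > 1,
               b$log_tau_over_KA > b$log_tau_over_KA[b$ligand == "carbachol"])
})

test_that("bias factors follow the ddlog arithmetic and antisymmetry", {
  f <- ref_fused_params()
  f$construct <- f$receptor
  # oxotremorine, M2 vs M4 fusion, from tabulated parameters:
  # ddlog = [log tau + pKA] contrasts vs carbachol at each construct
  bf <- compute_bias_factor(f, "oxotremorine", "M2", "M4")
  dd_oracle <- (log10(2.799) + 7.64 - (log10(1.41) + 6.6)) -
    (log10(0.994) + 7.95 - (log10(0.897) + 7.1))
  expect_equal(bf$ddlog, dd_oracle, tolerance = 1e-12)
  expect_equal(bf$ddlog, 0.443, tolerance = 1e-3)
  expect_equal(bf$factor, 2.8, tolerance = 0.01)
  # self-comparison
  expect_equal(compute_bias_factor(f, "oxotremorine", "M2", "M2")$factor, 1)
  # antisymmetry on random inputs
  set.seed(77)
  for (i in 1:10) {
    p <- data.frame(construct = rep(c("A", "B"), each = 2),
                    ligand = rep(c("carbachol", "x"), 2),
                    tau = 10^runif(4, -1, 1), pKA = runif(4, 5, 9))
    ab <- compute_bias_factor(p, "x", "A", "B")$factor
    ba <- compute_bias_factor(p, "x", "B", "A")$factor
    expect_equal(ab * ba, 1, tolerance = 1e-12)
  }
  # tau = 0 anywhere -> undefined
  f0 <- f
  bf0 <- compute_bias_factor(f0, "JR6", "M2", "M4")
  expect_true(is.na(bf0$factor))
})

test_that("ddlog is invariant to a constant shift of log(tau/KA)", {
  p <- data.frame(construct = rep(c("A", "B"), each = 2),
                  ligand = rep(c("carbachol", "x"), 2),
                  tau = c(1, 3, 0.5, 2), pKA = c(6, 7, 6.5, 7.5))
  d1 <- compute_bias_factor(p, "x", "A", "B")$ddlog
  p2 <- p
  p2$pKA[p2$construct == "A"] <- p2$pKA[p2$construct == "A"] + 1.7
  d2 <- compute_bias_factor(p2, "x", "A", "B")$ddlog
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("construct rankings reproduce published orderings with ties", {
  f <- ref_fused_params()
  f$construct <- f$receptor
  rank_of <- function(lig)
    rank_constructs(f[f$ligand == lig, ])
  # arecoline: M2 > M4 = M3 > M5 > M1
  r <- rank_of("arecoline")
  expect_identical(r$display, "M2 > M4 = M3 > M5 > M1")
  # xanomeline: strict order M2 > M5 > M4 > M1 > M3
  expect_identical(rank_of("xanomeline")$display, "M2 > M5 > M4 > M1 > M3")
  # McN-A-343: M2 > M4 > M5 > M1 > M3
  expect_identical(rank_of("McN-A-343")$display, "M2 > M4 > M5 > M1 > M3")
  # oxotremorine: M2 > M5 > M1 = M3 > M4
  expect_identical(rank_of("oxotremorine")$display, "M2 > M5 > M1 = M3 > M4")
  # all-equal RAi -> a single tie group
  eq <- data.frame(construct = c("A", "B", "C"), RAi = c(2, 2, 2))
  expect_equal(rank_constructs(eq)$tie_group, c(1L, 1L, 1L))
})

test_that("compare_groups flags known differences and not identical groups", {
  # identical groups: no flags
  set.seed(91)
  v <- rnorm(9)
  cg <- compare_groups(c(v, v), rep(c("a", "b"), each = 9))
  expect_false(any(cg$tukey$significant))
  # < 3 replicates: flags withheld with warning
  expect_warning(
    cg2 <- compare_groups(c(1, 2, 1.5, 2.5), c("a", "a", "b", "b")),
    "withheld")
  expect_true(cg2$flags_withheld)
  # published pKA contrast (co-transfected vs fused M2, oxotremorine):
  # groups simulated from the printed means/SDs separate cleanly
  set.seed(92)
  g1 <- rnorm(3, 6.26, 0.10); g2 <- rnorm(3, 7.64, 0.08)
  cg3 <- compare_groups(c(g1, g2), rep(c("cotx", "fused"), each = 3))
  expect_lt(cg3$anova_p, 0.05)
  expect_true(all(cg3$tukey$significant))
})

test_that("compare_groups separates tau 2.8 from 1.41 with high power", {
  # 3-experiment groups at 3% CV on the log scale, 500 simulations
  n_sim <- 500
  hits <- 0L
  set.seed(93)
  for (i in seq_len(n_sim)) {
    g1 <- log10(2.8 * (1 + rnorm(3, 0, 0.03)))
    g2 <- log10(1.41 * (1 + rnorm(3, 0, 0.03)))
    cg <- compare_groups(c(g1, g2), rep(c("a", "b"), each = 3))
    if (!is.null(cg$tukey) && all(cg$tukey$significant)) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.95)
})
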