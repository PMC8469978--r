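#' Step 1: estimate the system maximal response from internal standards
#'
#' Simultaneous least-squares fit of the operational model to the
#' concentration-response curves of several internal-standard agonists at
#' one (construct, pathway), sharing a single system maximum \eqn{E_{max}}
#' while each standard keeps its own \eqn{(\tau, pK_A)}.
#'
#' With a unit transducer slope every curve is a two-parameter hyperbola, so
#' the profiled sum of squares is *exactly flat* in \eqn{E_{max}} above the
#' largest apparent maximum: for any ceiling at least that high, each
#' standard's \eqn{(\tau, K_A)} can absorb the change. Functional data of
#' this design therefore identify \eqn{E_{max}} only as a lower bound. This
#' estimator makes that explicit: it profiles the global SSE over
#' \eqn{E_{max}} and reports the smallest value statistically consistent
#' with the unconstrained fit (an F-test-based lower confidence edge). When
#' a full agonist (\eqn{\tau \to \infty}) is among the standards the edge
#' equals that curve's plateau. Quantities used for bias analysis —
#' \eqn{\Delta\log(\tau/K_A)}, RAi, bias factors — are invariant to where on
#' the flat ridge the ceiling is placed (the \eqn{E_{max}}-dependent term of
#' \eqn{\log(\tau/K_A)} is common to all ligands at a construct and cancels
#' in differences); individual \eqn{\tau} and \eqn{pK_A} values are
#' conventional given the adopted ceiling. To reproduce a published
#' parameterization, fix the ceiling explicitly in [fit_operational()].
#'
#' A single curve (or a panel of equi-efficacious standards) leaves even the
#' lower edge degenerate with the curve's own plateau, so such input is
#' refused.
#'
#' @param panel list of [conc_response_series()] for the internal standards
#'   (the classical choice is carbachol, oxotremorine and pilocarpine);
#'   multiple experiments per ligand may be included.
#' @param variant baseline convention as in [operational_response()].
#' @param min_spread minimum relative spread of the standards' apparent
#'   maxima (range/mean) below which the fit is refused as non-identifiable.
#' @param conf_level confidence level of the profile-based lower edge.
#' @return An object of class `system_emax_fit` with `system_emax` (the
#'   profile edge), `se` (NA: the upper side is unbounded), per-series
#'   `(tau, pKA)` at the adopted ceiling, the SSE `profile`, and
#'   `ridge = TRUE` flagging the one-sided identifiability.
#' @export
fit_system_emax <- function(panel, variant = c("rebased", "plain"),
                            min_spread = 0.05, conf_level = 0.95) {
  variant <- match.arg(variant)
  if (inherits(panel, "conc_response_series")) panel <- list(panel)
  if (length(panel) < 2)
    stop("E_MAX is not identifiable from a single curve: the likelihood is flat ",
         "along the ridge E_MAX*tau/(tau+1) = const; supply >= 2 internal ",
         "standards with distinguishable apparent maxima")
  ligs <- vapply(panel, function(s) s$ligand, character(1))
  if (length(unique(ligs)) < 2)
    stop("supply curves for at least 2 distinct internal-standard ligands")

  hills <- lapply(panel, fit_hill)
  emx <- vapply(hills, function(h) h$emax_prime, numeric(1))
  if ((max(emx) - min(emx)) / mean(emx) < min_spread)
    stop("E_MAX not identifiable from standards: apparent maxima spread ",
         sprintf("%.1f%%", 100 * (max(emx) - min(emx)) / mean(emx)),
         " of the mean is below ", sprintf("%.0f%%", 100 * min_spread))

  sse_at <- function(emax) {
    sum(vapply(panel, function(s)
      .fit_operational_one(s, emax, variant, skip_flat = TRUE)$sse,
      numeric(1)))
  }
  n <- sum(vapply(panel, function(s) length(series_xy(s)$y), numeric(1)))
  npar <- 2 * length(panel) + 1
  dof <- n - npar

  edge0 <- max(emx)                 # plateau bound: ceiling cannot be lower
  shelf <- edge0 * 4                # deep on the flat shelf
  sse_shelf <- sse_at(shelf)
  # F-based acceptance threshold for the 1-parameter profile, with an
  # absolute floor so noise-free data (sse ~ 0) behave sensibly
  yscale <- sum(vapply(panel, function(s) sum(series_xy(s)$y^2), numeric(1)))
  thr <- sse_shelf * (1 + stats::qf(conf_level, 1, dof) / dof) +
    1e-9 * yscale
  lo <- edge0 * 1.0005; hi <- shelf
  if (sse_at(lo) <= thr) {
    emax_hat <- lo
  } else {
    for (i in 1:40) {             # bisect the profile crossing
      mid <- sqrt(lo * hi)
      if (sse_at(mid) > thr) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-6) break
    }
    emax_hat <- hi
  }

  per <- lapply(panel, function(s) {
    f <- .fit_operational_one(s, emax_hat, variant, skip_flat = TRUE)
    list(ligand = s$ligand, experiment_id = s$experiment_id,
         tau = f$tau, pKA = f$pKA, se = f$se)
  })
  prof_grid <- edge0 * c(1.001, 1.01, 1.05, 1.1, 1.25, 1.5, 2, 3, 4)
  profile <- data.frame(system_emax = prof_grid,
                        sse = vapply(prof_grid, sse_at, numeric(1)))
  structure(
    list(system_emax = emax_hat, se = NA_real_, per_series = per,
         variant = variant, ridge = TRUE, profile = profile,
         sse = sse_at(emax_hat), sse_shelf = sse_shelf, dof = dof,
         conf_level = conf_level),
    class = "system_emax_fit")
}

#' @export
print.system_emax_fit <- function(x, ...) {
  cat(sprintf("System E_MAX >= %.3g (profile lower edge at %.0f%% confidence)\n",
              x$system_emax, 100 * x$conf_level))
  cat("  note: E_MAX is identified only as a lower bound from unit-slope curves;\n",
      " bias quantities (RAi, ddlog(tau/KA)) are invariant to the ceiling choice\n",
      sep = "")
  for (p in x$per_series)
    cat(sprintf("  %-14s [%s]  tau = %.3g, pKA = %.3g\n",
                p$ligand, p$experiment_id, p$tau, p$pKA))
  invisible(x)
}

#' Step 2: fit the operational model with the system maximum fixed
#'
#' Fits \eqn{(\tau, pK_A)} by least squares to one concentration-response
#' series with \eqn{E_{max}} fixed (normally to the value estimated from
#' internal standards by [fit_system_emax()]). A series flagged flat by
#' [flat_test()] is reported with `tau = 0` and `pKA = NA` ("not
#' calculated"), the convention for agonists that fail to stimulate the
#' pathway. When given a list of series (independent experiments), each is
#' fitted separately and the across-experiment mean and SD are attached.
#'
#' @param series a [conc_response_series()] or a list of them.
#' @param system_emax the fixed system maximal response.
#' @param variant baseline convention as in [operational_response()].
#' @return An `operational_fit` (single series) or `operational_fit_set`
#'   (list of series) object.
#' @export
fit_operational <- function(series, system_emax,
                            variant = c("rebased", "plain")) {
  variant <- match.arg(variant)
  if (inherits(series, "conc_response_series")) {
    return(.fit_operational_one(series, system_emax, variant))
  }
  fits <- lapply(series, .fit_operational_one, system_emax = system_emax,
                 variant = variant)
  taus <- vapply(fits, function(f) f$tau, numeric(1))
  pKAs <- vapply(fits, function(f) f$pKA, numeric(1))
  structure(
    list(fits = fits, system_emax = system_emax, variant = variant,
         tau = mean(taus), tau_sd = stats::sd(taus),
         pKA = if (all(is.na(pKAs))) NA_real_ else mean(pKAs, na.rm = TRUE),
         pKA_sd = if (all(is.na(pKAs))) NA_real_ else
           stats::sd(pKAs, na.rm = TRUE),
         n_experiments = length(fits)),
    class = "operational_fit_set")
}

.fit_operational_one <- function(series, system_emax, variant,
                                 skip_flat = FALSE) {
  xy <- series_xy(series)
  ft <- if (skip_flat) list(p_value = 0) else flat_test(series)
  if (ft$p_value >= 0.05) {
    return(structure(
      list(tau = 0, pKA = NA_real_, system_emax = system_emax,
           emax_source = "fixed_input", variant = variant,
           se = c(tau = NA_real_, pKA = NA_real_),
           no_response = TRUE, flat_p = ft$p_value,
           fitted = rep(1, length(xy$y)), residuals = xy$y - 1,
           data = xy, series = series, method = "flat"),
      class = "operational_fit"))
  }
  h <- .hill_ls(xy$x, xy$y, fix_nH = 1)
  start <- tryCatch({
    op <- hill_to_operational(
      list(pEC50 = h$pEC50, emax_prime = min(h$emax_prime, 0.99 * system_emax)),
      system_emax, variant = variant)
    c(log10(max(op$tau, 1e-3)), op$pKA)
  }, error = function(e) c(0, h$pEC50 - log10(2)))

  best <- NULL
  for (dt in c(0, -0.5, 0.5)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ operational_response(x, system_emax, 10^ltau, pKA, variant = variant),
      data = list(x = xy$x, y = xy$y, system_emax = system_emax),
      start = list(ltau = min(max(start[1] + dt, -7.5), 5.5),
                   pKA = start[2]),
      lower = c(ltau = -8, pKA = -5), upper = c(ltau = 6, pKA = 20),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("operational fit failed to converge for series ", series$ligand,
         " [", series$experiment_id, "]")
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(ltau = NA_real_, pKA = NA_real_))
  tau <- 10^unname(cf["ltau"])
  structure(
    list(tau = tau, pKA = unname(cf["pKA"]), system_emax = system_emax,
         emax_source = "fixed_input", variant = variant,
         se = c(tau = unname(se["ltau"]) * log(10) * tau,
                pKA = unname(se["pKA"])),
         no_response = FALSE, flat_p = ft$p_value,
         fitted = stats::fitted(fit), residuals = stats::residuals(fit),
         sse = best$sse, data = xy, series = series, method = "ls"),
    class = "operational_fit")
}

#' @export
print.operational_fit_set <- function(x, ...) {
  cat(sprintf("Operational fit over %d experiments (E_MAX fixed at %.3g):\n",
              x$n_experiments, x$system_emax))
  cat(sprintf("  tau = %.3g +/- %.2g (SD),  pKA = %.3g +/- %.2g (SD)\n",
              x$tau, x$tau_sd, x$pKA, x$pKA_sd))
  invisible(x)
}
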