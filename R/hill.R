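#' Fit the Hill equation to a concentration-response series
#'
#' Least-squares fit of the fold-over-basal Hill model (see
#' [hill_response()]) with the bottom fixed at 1. Replicates are fitted as
#' individual points. A series whose response is not distinguishable from the
#' basal level (extra-sum-of-squares F-test against a constant model,
#' p >= 0.05) is flagged `no_response` with `emax_prime` pinned to 1.
#'
#' @param series a [conc_response_series()].
#' @param fix_nH optionally fix the Hill coefficient (e.g. `fix_nH = 1`).
#' @return An object of class `hill_fit` with components `pEC50`,
#'   `emax_prime`, `nH`, standard errors, fitted values and residuals.
#' @export
fit_hill <- function(series, fix_nH = NULL) {
  stopifnot(inherits(series, "conc_response_series"))
  xy <- series_xy(series)
  if (length(unique(xy$x)) < 4)
    stop("at least 4 distinct concentrations are required for a Hill fit")

  ft <- flat_test(series)
  if (ft$p_value >= 0.05) {
    return(structure(
      list(pEC50 = NA_real_, emax_prime = 1, nH = NA_real_,
           se = c(pEC50 = NA_real_, emax_prime = NA_real_, nH = NA_real_),
           no_response = TRUE, flat_p = ft$p_value,
           fitted = rep(mean(xy$y), length(xy$y)),
           residuals = xy$y - mean(xy$y),
           data = xy, series = series, convInfo = NULL),
      class = "hill_fit"))
  }

  fit <- .hill_ls(xy$x, xy$y, fix_nH = fix_nH)
  if (is.null(fit))
    stop("model mismatch (possibly biphasic): Hill fit failed to converge on a ",
         "series that is not flat")
  structure(
    c(fit,
      list(no_response = FALSE, flat_p = ft$p_value,
           data = xy, series = series)),
    class = "hill_fit")
}

# core least-squares engine shared by fit_hill and flat_test.
# Multi-start Levenberg-Marquardt on (pEC50, emax_prime, nH) with bounds
# emax_prime >= 1, nH in [0.2, 6]. Returns NULL if every start fails.
.hill_ls <- function(x, y, fix_nH = NULL) {
  lx <- -log10(x)
  p0 <- .hill_start(x, y)
  starts <- list(p0)
  for (d in c(-1, 1)) starts <- c(starts, list(c(p0[1] + d, p0[2], p0[3])))
  if (is.null(fix_nH))
    for (n0 in c(0.5, 2)) starts <- c(starts, list(c(p0[1], p0[2], n0)))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch({
      if (is.null(fix_nH)) {
        minpack.lm::nlsLM(
          y ~ 1 + (em - 1) * x^nH / (10^(-pec * nH) + x^nH),
          start = list(pec = s[1], em = max(s[2], 1.001), nH = s[3]),
          lower = c(pec = min(lx) - 3, em = 1, nH = 0.2),
          upper = c(pec = max(lx) + 3, em = Inf, nH = 6),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                               ptol = 1e-12))
      } else {
        nHf <- fix_nH
        minpack.lm::nlsLM(
          y ~ 1 + (em - 1) * x^nHf / (10^(-pec * nHf) + x^nHf),
          start = list(pec = s[1], em = max(s[2], 1.001)),
          lower = c(pec = min(lx) - 3, em = 1),
          upper = c(pec = max(lx) + 3, em = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                               ptol = 1e-12))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(NULL)

  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  nH_val <- if (is.null(fix_nH)) unname(cf["nH"]) else fix_nH
  nH_se <- if (is.null(fix_nH)) unname(se["nH"]) else NA_real_
  list(pEC50 = unname(cf["pec"]), emax_prime = unname(cf["em"]), nH = nH_val,
       se = c(pEC50 = unname(se["pec"]), emax_prime = unname(se["em"]),
              nH = nH_se),
       fitted = stats::fitted(fit), residuals = stats::residuals(fit),
       sse = best$sse, convInfo = fit$convInfo)
}

.hill_start <- function(x, y) {
  ybar <- tapply(y, x, mean)
  xs <- as.numeric(names(ybar))
  em0 <- max(max(ybar), 1.05)
  half <- 1 + (em0 - 1) / 2
  above <- which(ybar >= half)
  pec0 <- if (length(above)) -log10(xs[min(above)]) else -log10(stats::median(xs))
  c(pec0, em0, 1)
}

#' Test a concentration-response series for absence of coupling
#'
#' Extra-sum-of-squares F-test of the Hill model against a constant
#' (response-independent-of-concentration) model. A p-value >= 0.05 yields
#' the verdict `"no coupling"`; this is the criterion used both to detect
#' constructs whose receptors do not engage a pathway (flat cAMP curves at
#' fused constructs) and agonists that fail to stimulate a response
#' (tau = 0 rows).
#'
#' @param series a [conc_response_series()].
#' @return A list of class `flat_test` with `p_value`, `F_statistic`,
#'   `verdict` (`"coupled"` or `"no coupling"`), and the two SSEs.
#' @export
flat_test <- function(series) {
  stopifnot(inherits(series, "conc_response_series"))
  xy <- series_xy(series)
  n <- length(xy$y)
  sse0 <- sum((xy$y - mean(xy$y))^2)
  fit <- .hill_ls(xy$x, xy$y)
  sse1 <- if (is.null(fit)) sse0 else min(fit$sse, sse0)
  df0 <- n - 1
  df1 <- n - 3
  if (sse0 <= 1e-18 * n) {
    # constant model already perfect: nothing to explain
    Fst <- 0; p <- 1
  } else if (df1 <= 0 || sse1 <= 0) {
    Fst <- Inf; p <- 0
  } else {
    Fst <- ((sse0 - sse1) / (df0 - df1)) / (sse1 / df1)
    Fst <- max(Fst, 0)
    p <- stats::pf(Fst, df0 - df1, df1, lower.tail = FALSE)
  }
  structure(list(F_statistic = Fst, p_value = p,
                 verdict = if (p >= 0.05) "no coupling" else "coupled",
                 sse_constant = sse0, sse_hill = sse1, n = n),
            class = "flat_test")
}

#' @export
print.flat_test <- function(x, ...) {
  cat(sprintf("Flat test: %s (F = %.3g, p = %.3g, n = %d)\n",
              x$verdict, x$F_statistic, x$p_value, x$n))
  invisible(x)
}
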