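#' Specific binding and free radioligand concentration
#'
#' Averages replicates per point, subtracts nonspecific from total binding,
#' converts counts to molar equivalents in the incubation volume, and obtains
#' the free radioligand concentration by subtracting specifically bound
#' ligand from the added concentration. Points where the averaged nonspecific
#' exceeds total binding are excluded with a warning; a non-positive free
#' concentration (depletion too severe for a simple binding isotherm) is an
#' error.
#'
#' @param series a [saturation_series()].
#' @return A data.frame with one row per retained concentration: `added`
#'   and `free` (molar), `specific_conc` (molar equivalents),
#'   `specific_pmol_mg` (pmol specifically bound per mg protein), and
#'   `excluded` flags carried as an attribute.
#' @export
specific_binding <- function(series) {
  stopifnot(inherits(series, "saturation_series"))
  tot <- rowMeans(series$total_dpm, na.rm = TRUE)
  ns <- rowMeans(series$nonspecific_dpm, na.rm = TRUE)
  spec_dpm <- tot - ns
  bad <- spec_dpm < 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with nonspecific > total binding excluded")
    spec_dpm[bad] <- NA_real_
  }
  spec_conc <- dpm_to_molar(spec_dpm, series$specific_activity,
                            series$volume_L, series$counting_efficiency)
  free <- series$added_conc - spec_conc
  if (any(free <= 0, na.rm = TRUE))
    stop("free radioligand concentration <= 0: ligand depletion too severe ",
         "for the simple binding isotherm")
  mol <- spec_conc * series$volume_L
  out <- data.frame(added = series$added_conc, free = free,
                    specific_conc = spec_conc,
                    specific_pmol_mg = mol * 1e12 / series$protein_mg)
  attr(out, "excluded") <- bad
  out[!bad, , drop = FALSE]
}

#' Fit a saturation binding isotherm
#'
#' Least-squares fit of the rectangular hyperbola
#' \eqn{y = B_{max} x / (K_D + x)} to specific binding (pmol/mg protein)
#' versus free radioligand concentration, as prepared by
#' [specific_binding()]. \eqn{K_D} is estimated and reported on the negative
#' log10 molar scale (`pKD`).
#'
#' @param series a [saturation_series()].
#' @return An object of class `saturation_fit` with `pKD`, `BMAX`
#'   (pmol/mg protein), standard errors and a `poorly_constrained` flag set
#'   when the fitted \eqn{K_D} falls outside the measured free-concentration
#'   window by more than a factor of 10.
#' @export
fit_saturation <- function(series) {
  sb <- specific_binding(series)
  if (nrow(sb) < 4)
    stop("at least 4 points with positive specific binding are required")
  if (all(abs(sb$specific_pmol_mg) < 1e-12 * max(1, max(sb$specific_pmol_mg))) ||
      max(sb$specific_pmol_mg) <= 0)
    stop("no specific binding detected: saturation fit refused")

  x <- sb$free; y <- sb$specific_pmol_mg
  pkd0 <- -log10(stats::median(x))
  bmax0 <- max(y) * 1.2
  best <- NULL
  for (d in c(0, -1, 1)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ bmax * x / (10^(-pkd) + x),
      start = list(bmax = bmax0, pkd = pkd0 + d),
      lower = c(bmax = 0, pkd = -log10(max(x)) - 6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("saturation fit failed to converge")
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(bmax = NA_real_, pkd = NA_real_))
  kd <- 10^(-cf[["pkd"]])
  poorly <- kd < min(x) / 10 || kd > max(x) * 10
  if (poorly)
    warning("poorly constrained: fitted KD (", signif(kd, 3),
            " M) lies outside the measured free-concentration window")
  structure(
    list(pKD = cf[["pkd"]], BMAX = cf[["bmax"]],
         se = c(pKD = unname(se["pkd"]), BMAX = unname(se["bmax"])),
         poorly_constrained = poorly, sse = best$sse,
         data = sb, series = series),
    class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation fit: pKD = %.3f +/- %.3f, BMAX = %.3g +/- %.2g pmol/mg\n",
              x$pKD, x$se["pKD"], x$BMAX, x$se["BMAX"]))
  if (x$poorly_constrained) cat("  (flag: poorly constrained KD)\n")
  invisible(x)
}
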