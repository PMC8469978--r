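#' Fit a radioligand competition binding curve
#'
#' Fits one-site and two-site competition models to responses expressed as
#' percent of radioligand binding in the absence of competitor:
#' \deqn{y = 100 - \frac{100\,x}{x + IC_{50}}}
#' \deqn{y = 100 - \frac{(100 - f_{low})\,x}{x + IC_{50,high}}
#'            - \frac{f_{low}\,x}{x + IC_{50,low}}}
#' The two-site model is selected only when the extra-sum-of-squares F-test
#' prefers it at p < 0.05. Each IC50 is converted to an inhibition constant
#' by the Cheng-Prusoff correction
#' \eqn{K_I = IC_{50} / (1 + [D]/K_D)} with \eqn{[D]} the radioligand
#' concentration and \eqn{K_D} its saturation-binding dissociation constant.
#' The fraction of low-affinity sites is fitted on a logit scale within
#' [1, 99]% to avoid boundary degeneracy. A diagnostic one-site fit with a
#' free bottom plateau triggers an "incomplete inhibition" warning when the
#' plateau is significantly above 20% of control.
#'
#' @param series a [conc_response_series()] whose responses are percent of
#'   control binding.
#' @param radioligand_conc radioligand concentration \eqn{[D]} in molar
#'   (default 1 nM).
#' @param radioligand_pKD radioligand pKD from saturation binding; with
#'   `radioligand_conc = 0` the correction degenerates to \eqn{K_I = IC_{50}}.
#' @return An object of class `competition_fit`: `model` (`"one_site"` or
#'   `"two_site"`), `pIC50_high`/`pIC50_low`, `f_low` (percent), the
#'   Cheng-Prusoff-corrected `pKI_high`/`pKI_low`, and the model-comparison
#'   `F_statistic` and `p_value`. One-site fits populate only the `_low`
#'   slots.
#' @export
fit_competition <- function(series, radioligand_conc = 1e-9,
                            radioligand_pKD = 9.5) {
  stopifnot(inherits(series, "conc_response_series"))
  xy <- series_xy(series)
  x <- xy$x; y <- xy$y
  if (length(unique(x)) < 4)
    stop("at least 4 distinct competitor concentrations are required")
  n <- length(y)

  one <- .comp_fit_one(x, y)
  two <- .comp_fit_two(x, y, one)

  if (!is.null(two) && two$sse < one$sse && n > 4) {
    Fst <- ((one$sse - two$sse) / 2) / (two$sse / (n - 4))
    p <- stats::pf(Fst, 2, n - 4, lower.tail = FALSE)
  } else {
    Fst <- 0; p <- 1
  }
  use_two <- is.finite(p) && p < 0.05

  cp <- function(pic50) {
    # Cheng-Prusoff on the log scale: pKI = pIC50 + log10(1 + [D]/KD)
    pic50 + log10(1 + radioligand_conc / 10^(-radioligand_pKD))
  }

  .comp_bottom_check(x, y, one)

  if (use_two) {
    out <- list(model = "two_site",
                pIC50_high = two$pic_high, pIC50_low = two$pic_low,
                f_low = two$f_low,
                pKI_high = cp(two$pic_high), pKI_low = cp(two$pic_low),
                se = two$se, F_statistic = Fst, p_value = p,
                sse = two$sse)
  } else {
    out <- list(model = "one_site",
                pIC50_high = NA_real_, pIC50_low = one$pic50,
                f_low = NA_real_,
                pKI_high = NA_real_, pKI_low = cp(one$pic50),
                se = one$se, F_statistic = Fst, p_value = p,
                sse = one$sse)
  }
  out$radioligand_conc <- radioligand_conc
  out$radioligand_pKD <- radioligand_pKD
  out$data <- xy
  out$series <- series
  structure(out, class = "competition_fit")
}

.comp_fit_one <- function(x, y) {
  pic0 <- -log10(x[which.min(abs(y - 50))])
  best <- NULL
  for (d in c(0, -1, 1)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ 100 - 100 * x / (x + 10^(-pic)),
      start = list(pic = pic0 + d),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("one-site competition fit failed to converge")
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(pic = NA_real_))
  list(pic50 = stats::coef(best$fit)[["pic"]],
       se = c(pIC50 = unname(se["pic"])), sse = best$sse)
}

# two-site model parameterized as pic_low, dlog = pic_high - pic_low > 0,
# and logit of (f_low - 1)/98 so f_low stays in [1, 99]%
.comp_fit_two <- function(x, y, one) {
  f_model <- function(pic_low, dlog, lgf, x) {
    f <- 1 + 98 * stats::plogis(lgf)
    pic_high <- pic_low + dlog
    100 - (100 - f) * x / (x + 10^(-pic_high)) - f * x / (x + 10^(-pic_low))
  }
  starts <- list(c(one$pic50 - 0.5, 1, 0), c(one$pic50 - 1, 2, 0),
                 c(one$pic50, 0.5, 0))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ f_model(pic_low, dlog, lgf, x),
      start = list(pic_low = s[1], dlog = s[2], lgf = s[3]),
      lower = c(pic_low = -Inf, dlog = 1e-6, lgf = -20),
      upper = c(pic_low = Inf, dlog = 10, lgf = 20),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(NULL)
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     names(cf)))
  f_low <- 1 + 98 * stats::plogis(cf[["lgf"]])
  list(pic_low = cf[["pic_low"]], pic_high = cf[["pic_low"]] + cf[["dlog"]],
       f_low = f_low,
       se = c(pIC50_low = unname(se["pic_low"]),
              dlog = unname(se["dlog"]),
              f_low = 98 * stats::dlogis(cf[["lgf"]]) * unname(se["lgf"])),
       sse = best$sse)
}

# diagnostic: one-site with a free bottom plateau; warn when the plateau is
# significantly above 20% of control (agonists are expected to displace the
# radioligand completely)
.comp_bottom_check <- function(x, y, one) {
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ bot + (100 - bot) * (1 - x / (x + 10^(-pic))),
    start = list(bot = 5, pic = one$pic50),
    lower = c(bot = 0, pic = -Inf), upper = c(bot = 95, pic = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(invisible(NULL))
  cf <- stats::coef(fit)
  sse_free <- sum(stats::residuals(fit)^2)
  n <- length(y)
  if (n > 2 && one$sse > sse_free) {
    if (sse_free <= 1e-12 * one$sse) {
      p <- 0
    } else {
      Fst <- ((one$sse - sse_free) / 1) / (sse_free / (n - 2))
      p <- stats::pf(Fst, 1, n - 2, lower.tail = FALSE)
    }
    if (cf[["bot"]] > 20 && is.finite(p) && p < 0.05)
      warning("incomplete inhibition: bottom plateau ",
              sprintf("%.1f%%", cf[["bot"]]), " of control (p = ",
              signif(p, 2), ")")
  }
  invisible(NULL)
}

#' Cheng-Prusoff correction
#'
#' Converts a competition IC50 to an inhibition constant:
#' \eqn{K_I = IC_{50}/(1 + [D]/K_D)}. On the negative log scale this is
#' \eqn{pK_I = pIC_{50} + \log_{10}(1 + [D]/K_D)}, so the corrected affinity
#' constant is always at least as small as the IC50 (pKI >= pIC50).
#'
#' @param IC50 competition IC50, molar.
#' @param radioligand_conc radioligand concentration \eqn{[D]}, molar.
#' @param KD radioligand equilibrium dissociation constant, molar.
#' @return \eqn{K_I} in molar.
#' @export
cheng_prusoff <- function(IC50, radioligand_conc, KD) {
  if (any(IC50 <= 0) || any(KD <= 0) || any(radioligand_conc < 0))
    stop("IC50 and KD must be positive; radioligand concentration non-negative")
  IC50 / (1 + radioligand_conc / KD)
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("Competition fit: %s model (F = %.3g, p = %.3g)\n",
              x$model, x$F_statistic, x$p_value))
  if (x$model == "two_site") {
    cat(sprintf("  pKI(high) = %.3f, pKI(low) = %.3f, f_low = %.1f%%\n",
                x$pKI_high, x$pKI_low, x$f_low))
  } else {
    cat(sprintf("  pKI = %.3f (pIC50 = %.3f)\n", x$pKI_low, x$pIC50_low))
  }
  invisible(x)
}
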