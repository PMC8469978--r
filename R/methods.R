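# S3 methods for the fit classes

#' @export
print.hill_fit <- function(x, ...) {
  if (x$no_response) {
    cat(sprintf("Hill fit: no response (flat-test p = %.3g); E'MAX pinned to 1\n",
                x$flat_p))
  } else {
    cat(sprintf("Hill fit: pEC50 = %.3f +/- %.3f, E'MAX = %.3g +/- %.2g, nH = %.3g\n",
                x$pEC50, x$se["pEC50"], x$emax_prime, x$se["emax_prime"],
                x$nH))
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...)
  c(pEC50 = object$pEC50, emax_prime = object$emax_prime, nH = object$nH)

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
fitted.hill_fit <- function(object, ...) object$fitted

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.list(newdata)) newdata$x else newdata
  if (object$no_response) return(rep(1, length(x)))
  hill_response(x, object$pEC50, object$emax_prime, object$nH)
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  if (!object$no_response)
    cat(sprintf("  SSE %.4g on %d points; flat-test p = %.3g\n",
                object$sse, length(object$data$y), object$flat_p))
  invisible(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  .plot_curve_fit(x$data, function(g) predict(x, g),
                  main = sprintf("Hill fit: %s", x$series$ligand), ...)
}

#' @export
print.operational_fit <- function(x, ...) {
  if (x$no_response) {
    cat(sprintf("Operational fit: no response (tau = 0, pKA not calculated; flat-test p = %.3g)\n",
                x$flat_p))
  } else {
    cat(sprintf("Operational fit (E_MAX fixed at %.3g, %s): tau = %.3g +/- %.2g, pKA = %.3f +/- %.3f\n",
                x$system_emax, x$variant, x$tau, x$se["tau"], x$pKA,
                x$se["pKA"]))
  }
  invisible(x)
}

#' @export
coef.operational_fit <- function(object, ...)
  c(tau = object$tau, pKA = object$pKA, system_emax = object$system_emax)

#' @export
residuals.operational_fit <- function(object, ...) object$residuals

#' @export
predict.operational_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.list(newdata)) newdata$x else newdata
  if (object$no_response || object$tau <= 0) return(rep(1, length(x)))
  operational_response(x, object$system_emax, object$tau, object$pKA,
                       variant = object$variant)
}

#' @export
plot.operational_fit <- function(x, ...) {
  .plot_curve_fit(x$data, function(g) predict(x, g),
                  main = sprintf("Operational fit: %s",
                                 if (!is.null(x$series)) x$series$ligand
                                 else ""), ...)
}

#' @export
coef.operational_fit_set <- function(object, ...)
  c(tau = object$tau, pKA = object$pKA, system_emax = object$system_emax)

#' @export
coef.saturation_fit <- function(object, ...)
  c(pKD = object$pKD, BMAX = object$BMAX)

#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$free else
    if (is.list(newdata)) newdata$x else newdata
  object$BMAX * x / (10^(-object$pKD) + x)
}

#' @export
plot.saturation_fit <- function(x, ...) {
  dat <- list(x = x$data$free, y = x$data$specific_pmol_mg)
  .plot_curve_fit(dat, function(g) predict(x, g),
                  main = "Saturation binding", log_y = FALSE,
                  ylab = "specific binding (pmol/mg)", ...)
}

#' @export
coef.competition_fit <- function(object, ...) {
  if (object$model == "two_site")
    c(pKI_high = object$pKI_high, pKI_low = object$pKI_low,
      f_low = object$f_low)
  else c(pKI = object$pKI_low)
}

#' @export
predict.competition_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.list(newdata)) newdata$x else newdata
  if (object$model == "two_site") {
    f <- object$f_low
    100 - (100 - f) * x / (x + 10^(-object$pIC50_high)) -
      f * x / (x + 10^(-object$pIC50_low))
  } else {
    100 - 100 * x / (x + 10^(-object$pIC50_low))
  }
}

#' @export
plot.competition_fit <- function(x, ...) {
  .plot_curve_fit(x$data, function(g) predict(x, g),
                  main = sprintf("Competition: %s (%s)",
                                 x$series$ligand, x$model),
                  ylab = "% of control binding", ...)
}

# shared scatter + fitted-curve plot on a log concentration axis
.plot_curve_fit <- function(dat, predict_fn, main = "", log_y = TRUE,
                            ylab = "response (fold over basal)", ...) {
  graphics::plot(dat$x, dat$y, log = "x", xlab = "concentration (M)",
                 ylab = ylab, main = main, pch = 16,
                 col = grDevices::grey(0.3), ...)
  grid <- 10^seq(log10(min(dat$x)), log10(max(dat$x)), length.out = 200)
  graphics::lines(grid, predict_fn(grid), col = "firebrick", lwd = 2)
  invisible(NULL)
}
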