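#' Hill concentration-response function
#'
#' Evaluates the four-parameter logistic with the bottom fixed at the basal
#' level of 1 (responses are expressed fold over basal):
#' \deqn{y = 1 + (E'_{max} - 1) \frac{x^{n_H}}{EC_{50}^{n_H} + x^{n_H}}}
#' with \eqn{EC_{50} = 10^{-pEC_{50}}}.
#'
#' @param x agonist concentration in molar (vector, values >= 0).
#' @param pEC50 negative log10 molar concentration of half-maximal effect.
#' @param emax_prime apparent maximal response \eqn{E'_{max}} (fold over
#'   basal, >= 1).
#' @param nH Hill coefficient (> 0).
#' @return Response in fold over basal, same length as `x`.
#' @examples
#' hill_response(10^-7, pEC50 = 7, emax_prime = 18, nH = 1)  # midpoint 9.5
#' @export
hill_response <- function(x, pEC50, emax_prime, nH = 1) {
  if (any(x < 0)) stop("concentrations must be non-negative")
  if (nH <= 0) stop("Hill coefficient must be positive")
  if (emax_prime < 1) stop("emax_prime must be >= 1 (fold over basal)")
  ec50 <- 10^(-pEC50)
  xn <- x^nH
  1 + (emax_prime - 1) * xn / (ec50^nH + xn)
}

#' Operational model of agonism
#'
#' Evaluates the operational (Black-Leff) transduction model
#' \deqn{y = \frac{E_{max}\,\tau\,x}{K_A + (\tau + 1) x}}
#' where \eqn{E_{max}} is the maximal response of the system, \eqn{\tau} the
#' operational efficacy, and \eqn{K_A = 10^{-pK_A}} the agonist equilibrium
#' dissociation constant at the signalling-competent conformation.
#'
#' Two baseline conventions are provided. The default, `variant = "rebased"`,
#' anchors the curve at the basal response of 1 (data are fold over basal):
#' \eqn{y = 1 + (E_{max} - 1)\tau x / (K_A + (\tau+1) x)}. The `"plain"`
#' variant is the bare model above, whose plateau is
#' \eqn{E_{max}\tau/(\tau+1)}; it is the convention under which published
#' parameter tables for these assays are internally consistent
#' (\eqn{E'_{max} = E_{max}\tau/(\tau+1)} with \eqn{E'_{max}} inclusive of
#' basal). Both conventions share the potency relation
#' \eqn{pEC_{50} = pK_A + \log_{10}(1 + \tau)}.
#'
#' @param x agonist concentration in molar (vector, values >= 0).
#' @param system_emax maximal response of the system (fold over basal).
#' @param tau operational efficacy (> 0).
#' @param pKA negative log10 molar operational dissociation constant.
#' @param variant baseline convention, `"rebased"` (default) or `"plain"`.
#' @return Response in fold over basal, same length as `x`.
#' @export
operational_response <- function(x, system_emax, tau, pKA,
                                 variant = c("rebased", "plain")) {
  variant <- match.arg(variant)
  if (any(x < 0)) stop("concentrations must be non-negative")
  if (tau <= 0) stop("tau must be positive")
  KA <- 10^(-pKA)
  core <- tau * x / (KA + (tau + 1) * x)
  if (variant == "rebased") 1 + (system_emax - 1) * core
  else system_emax * core
}

#' Closed-form conversion between Hill and operational parameters
#'
#' When the Hill coefficient equals one, the Hill curve and the operational
#' model describe the same hyperbola and the operational parameters follow in
#' closed form from \eqn{(pEC_{50}, E'_{max})} and the system maximum:
#' \deqn{\tau = \frac{E'_{max} - 1}{E_{max} - E'_{max}} \ \mathrm{(rebased)}
#'   \quad\mathrm{or}\quad
#'   \tau = \frac{E'_{max}}{E_{max} - E'_{max}} \ \mathrm{(plain)}}
#' \deqn{pK_A = pEC_{50} - \log_{10}(1 + \tau)}
#'
#' @param hill a [hill_fit] object, or a list/vector with elements `pEC50`,
#'   `emax_prime` and (optionally) `nH`.
#' @param system_emax system maximal response (must exceed `emax_prime`).
#' @param variant baseline convention as in [operational_response()].
#' @param nH_tol tolerance on `|nH - 1|` beyond which the closed form is
#'   refused (the conversion assumes a unit slope).
#' @return An object of class `operational_fit` with `tau` and `pKA`.
#' @export
hill_to_operational <- function(hill, system_emax,
                                variant = c("rebased", "plain"),
                                nH_tol = 0.2) {
  variant <- match.arg(variant)
  h <- as.list(hill)
  pEC50 <- h$pEC50
  emax_prime <- h$emax_prime
  nH <- if (is.null(h$nH) || is.na(h$nH)) 1 else h$nH
  if (abs(nH - 1) > nH_tol)
    stop("closed-form conversion requires a Hill coefficient near 1 (|nH - 1| <= ",
         nH_tol, "); got nH = ", format(nH))
  if (emax_prime >= system_emax)
    stop("emax_prime (", format(emax_prime), ") must be below the system maximum (",
         format(system_emax), "): tau is not identifiable when the apparent ",
         "maximum reaches the system ceiling")
  tau <- if (variant == "rebased") (emax_prime - 1) / (system_emax - emax_prime)
         else emax_prime / (system_emax - emax_prime)
  pKA <- pEC50 - log10(1 + tau)
  structure(
    list(tau = tau, pKA = pKA, system_emax = system_emax,
         emax_source = "fixed_input", variant = variant,
         se = c(tau = NA_real_, pKA = NA_real_),
         no_response = FALSE, method = "closed_form"),
    class = "operational_fit")
}

# inverse of the closed form: apparent Hill parameters of an operational curve
operational_to_hill <- function(system_emax, tau, pKA,
                                variant = c("rebased", "plain")) {
  variant <- match.arg(variant)
  emax_prime <- if (variant == "rebased")
    1 + (system_emax - 1) * tau / (tau + 1)
  else system_emax * tau / (tau + 1)
  list(pEC50 = pKA + log10(1 + tau), emax_prime = emax_prime, nH = 1)
}
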