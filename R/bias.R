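#' Relative intrinsic activity (RAi) against a reference agonist
#'
#' Computes intrinsic activity of each agonist relative to a reference
#' agonist (classically carbachol) at one (construct, pathway), oriented so
#' that a more potent/efficacious test agonist gives RAi > 1:
#' \deqn{RA_i = \frac{\tau_a / K_{A,a}}{\tau_{ref} / K_{A,ref}}
#'     = \frac{E'_{max,a} / EC_{50,a}}{E'_{max,ref} / EC_{50,ref}}}
#' The two routes coincide exactly when the Hill coefficient is one. Note the
#' orientation: published parameter tables in this field report RAi with the
#' test agonist in the numerator (the formula is sometimes printed
#' reciprocally); this implementation follows the tables.
#'
#' Standard deviations are propagated first-order on the log scale:
#' \eqn{\mathrm{var}(\log_{10} RA_i)} is the sum of the component variances
#' of \eqn{\log_{10}\tau} (or \eqn{\log_{10} E'_{max}}) and \eqn{pK_A} (or
#' \eqn{pEC_{50}}) for agonist and reference.
#'
#' @param params data.frame with one row per agonist at a single construct.
#'   For `method = "tau_ka"` it needs columns `ligand`, `tau`, `pKA` and
#'   optionally `tau_sd`, `pKA_sd`; for `method = "emax_ec50"` columns
#'   `ligand`, `emax_prime`, `pEC50` and optionally their `_sd`s. A column
#'   `nH` is checked against the unit-slope tolerance for the
#'   `"emax_ec50"` route.
#' @param reference name of the reference ligand (must appear in `params`).
#' @param method which parameter pair to use.
#' @param nH_tol tolerance on `|nH - 1|` for the `"emax_ec50"` route.
#' @return `params` with added columns `log_tau_over_KA` (or its
#'   \eqn{E'_{max}/EC_{50}} analogue), `RAi` and `RAi_sd`. Agonists with
#'   `tau = 0` (no response) get `RAi = 0`.
#' @export
compute_RAi <- function(params, reference = "carbachol",
                        method = c("tau_ka", "emax_ec50"), nH_tol = 0.2) {
  method <- match.arg(method)
  params <- as.data.frame(params)
  if (!reference %in% params$ligand)
    stop("reference ligand '", reference, "' not found in params")
  if (method == "tau_ka") {
    need <- c("tau", "pKA")
    logq <- ifelse(params$tau > 0, log10(params$tau) + params$pKA, -Inf)
    sd_log <- .rai_sd_log(params, "tau", "pKA")
  } else {
    need <- c("emax_prime", "pEC50")
    if (!is.null(params$nH) && any(abs(params$nH - 1) > nH_tol, na.rm = TRUE))
      stop("emax_ec50 route requires Hill coefficients within ", nH_tol,
           " of unity")
    logq <- log10(params$emax_prime) + params$pEC50
    sd_log <- .rai_sd_log(params, "emax_prime", "pEC50")
  }
  if (!all(need %in% names(params)))
    stop("params must contain columns: ", paste(need, collapse = ", "))
  iref <- match(reference, params$ligand)
  lr <- logq - logq[iref]
  rai <- 10^lr
  rai[!is.finite(logq)] <- 0
  sd_comb <- sqrt(sd_log^2 + sd_log[iref]^2)
  sd_comb[iref] <- sd_log[iref]  # self-comparison keeps its own scatter
  params$log_tau_over_KA <- logq
  params$RAi <- rai
  params$RAi_sd <- ifelse(rai > 0, rai * log(10) * sd_comb, 0)
  params
}

# SD of log10(scale parameter) + (log-scale location parameter)
.rai_sd_log <- function(params, scale_col, loc_col) {
  sc <- params[[paste0(scale_col, "_sd")]]
  lc <- params[[paste0(loc_col, "_sd")]]
  v <- rep(0, nrow(params))
  if (!is.null(sc))
    v <- v + ifelse(params[[scale_col]] > 0,
                    (sc / (params[[scale_col]] * log(10)))^2, 0)
  if (!is.null(lc)) v <- v + ifelse(is.na(lc), 0, lc^2)
  sqrt(v)
}

#' Bias factor between two receptor constructs
#'
#' Quantifies the preference of an agonist for construct A over construct B,
#' normalized to the reference agonist, as
#' \deqn{\Delta\log(\tau/K_A) = [\log_{10}\tau + pK_A]_{ligand}
#'   - [\log_{10}\tau + pK_A]_{ref} \quad \mathrm{per\ construct}}
#' \deqn{\Delta\Delta\log(\tau/K_A) = \Delta\log_A - \Delta\log_B, \qquad
#'   \mathrm{bias\ factor} = 10^{\Delta\Delta\log(\tau/K_A)}}
#' By construction factor(A,B) x factor(B,A) = 1, and the result is
#' invariant to any common shift of all log(tau/KA) values at a construct.
#'
#' @param params data.frame with columns `construct`, `ligand`, `tau`, `pKA`
#'   covering the ligand and reference at both constructs.
#' @param ligand test agonist name.
#' @param constructA,constructB construct labels to compare.
#' @param reference reference agonist name.
#' @return A list with `delta_log_A`, `delta_log_B`, `ddlog` and `factor`.
#'   Any `tau = 0` among the four cells makes the factor undefined (NA).
#' @export
compute_bias_factor <- function(params, ligand, constructA, constructB,
                                reference = "carbachol") {
  params <- as.data.frame(params)
  cell <- function(con, lig) {
    i <- which(params$construct == con & params$ligand == lig)
    if (length(i) != 1)
      stop("need exactly one row for (", con, ", ", lig, ")")
    c(tau = params$tau[i], pKA = params$pKA[i])
  }
  la <- cell(constructA, ligand); ra <- cell(constructA, reference)
  lb <- cell(constructB, ligand); rb <- cell(constructB, reference)
  if (any(c(la["tau"], ra["tau"], lb["tau"], rb["tau"]) <= 0)) {
    return(list(delta_log_A = NA_real_, delta_log_B = NA_real_,
                ddlog = NA_real_, factor = NA_real_,
                note = "undefined: tau = 0 in at least one cell"))
  }
  dA <- (log10(la["tau"]) + la["pKA"]) - (log10(ra["tau"]) + ra["pKA"])
  dB <- (log10(lb["tau"]) + lb["pKA"]) - (log10(rb["tau"]) + rb["pKA"])
  dd <- unname(dA - dB)
  list(delta_log_A = unname(dA), delta_log_B = unname(dB),
       ddlog = dd, factor = 10^dd)
}

#' Rank receptor constructs by relative intrinsic activity
#'
#' Orders constructs by descending RAi for one agonist and groups adjacent
#' constructs that cannot be separated statistically ("approximately equal").
#' When per-construct SDs are available (summary of n independent
#' experiments), adjacent pairs are compared by a pooled two-sample t-test
#' and declared tied at p >= 0.05; without any dispersion information a relative
#' difference below `tie_threshold` declares a tie.
#'
#' @param bias data.frame with columns `construct`, `RAi`, optionally
#'   `RAi_sd`, for one ligand.
#' @param n number of independent experiments behind each mean (default 3).
#' @param tie_threshold relative-difference fallback threshold.
#' @return A list with `order` (construct labels, descending RAi),
#'   `tie_group` (integer group per ordered construct) and a display string
#'   like `"M2 > M4 = M3 > M5 > M1"`.
#' @export
rank_constructs <- function(bias, n = 3, tie_threshold = 0.1) {
  bias <- as.data.frame(bias)
  ord <- order(-bias$RAi)
  b <- bias[ord, , drop = FALSE]
  k <- nrow(b)
  tie <- integer(k)
  tie[1] <- 1L
  has_sd <- !is.null(b$RAi_sd) && any(b$RAi_sd > 0, na.rm = TRUE)
  for (i in seq_len(k - 1)) {
    a <- b$RAi[i]; bb <- b$RAi[i + 1]
    tied <- if (has_sd) {
      # pooled two-sample t from summary statistics (n experiments per mean)
      s1 <- max(b$RAi_sd[i], 0, na.rm = TRUE)
      s2 <- max(b$RAi_sd[i + 1], 0, na.rm = TRUE)
      se <- sqrt((s1^2 + s2^2) / 2) * sqrt(2 / n)
      if (se == 0) {
        isTRUE(all.equal(a, bb))
      } else {
        tstat <- (a - bb) / se
        2 * stats::pt(abs(tstat), 2 * (n - 1), lower.tail = FALSE) >= 0.05
      }
    } else {
      a > 0 && (a - bb) / a < tie_threshold || (a == 0 && bb == 0)
    }
    tie[i + 1] <- if (tied) tie[i] else tie[i] + 1L
  }
  sep <- ifelse(tie[-1] == tie[-k], " = ", " > ")
  list(order = b$construct, tie_group = tie, RAi = b$RAi,
       display = paste0(b$construct,
                        c(sep, ""), collapse = ""))
}

#' Compare parameter groups by ANOVA with Tukey HSD post-test
#'
#' One-way ANOVA across groups of per-experiment parameter estimates,
#' followed (when the ANOVA rejects at p < 0.05) by Tukey's honestly
#' significant difference post-test. Parameters that live on a log scale
#' (EC50, KA, tau and quantities derived from them) should be passed as
#' logarithms. With fewer than 3 estimates in any group the flags are
#' withheld with a warning.
#'
#' @param values numeric vector of per-experiment estimates.
#' @param groups factor/character vector of the same length.
#' @return A list with `anova_p`, `tukey` (data.frame of pairwise
#'   comparisons with adjusted p-values and `significant` flags), and
#'   `flags_withheld`.
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  counts <- table(groups)
  withheld <- any(counts < 3)
  if (withheld)
    warning("fewer than 3 estimates in at least one group: ",
            "significance flags withheld")
  fit <- stats::aov(values ~ groups)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tukey <- NULL
  if (!withheld && is.finite(anova_p) && anova_p < 0.05) {
    tk <- stats::TukeyHSD(fit)$groups
    tukey <- data.frame(comparison = rownames(tk),
                        diff = tk[, "diff"],
                        p_adj = tk[, "p adj"],
                        significant = tk[, "p adj"] < 0.05,
                        row.names = NULL)
  } else if (!withheld) {
    cmb <- utils::combn(levels(groups), 2)
    tukey <- data.frame(
      comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
      diff = NA_real_, p_adj = NA_real_, significant = FALSE)
  }
  list(anova_p = anova_p, tukey = tukey, flags_withheld = withheld)
}
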