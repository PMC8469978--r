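#' Simulation configuration for virtual pharmacology experiments
#'
#' Captures the experimental design the simulator emulates: six-point
#' saturation binding (63-2000 pM radioligand) in quadruplicate, competition
#' binding at 1 nM radioligand in quadruplicate, and 9-point functional
#' concentration-response curves in triplicate (half-log steps centred on
#' the true pEC50), each repeated over independent experiments. Noise is
#' multiplicative Gaussian, parameterized by a coefficient of variation
#' (count-proportional scatter, as in radiometric assays). The functional
#' basal level is drawn uniformly between 2 and 3% of incorporated
#' radioactivity per experiment.
#'
#' @param seed integer RNG seed; the seed fully determines all output.
#' @param cv_functional per-point CV of functional responses (default 0.05).
#' @param cv_binding per-point CV of binding counts (default 0.03).
#' @param n_replicates_functional wells per concentration, functional
#'   assays (default 3).
#' @param n_replicates_binding wells per concentration, binding assays
#'   (default 4).
#' @param n_experiments independent experiments (default 3).
#' @param basal_range basal level range as fraction of incorporated
#'   radioactivity (default `c(0.02, 0.03)`).
#' @param incorporated_dpm total incorporated radioactivity per sample, dpm
#'   (arbitrary scale; fold-over-basal results are scale-free).
#' @param sat_conc added radioligand concentrations for saturation binding,
#'   molar.
#' @param radioligand_conc radioligand concentration in competition assays,
#'   molar.
#' @param ns_slope nonspecific binding as a fraction of added radioligand
#'   (linear in added; the default yields roughly 20% of total binding at
#'   1 nM under typical site densities).
#' @param specific_activity radioligand specific activity, Ci/mmol.
#' @param protein_mg membrane protein per sample, mg.
#' @param volume_L incubation volume, litres.
#' @param func_n_conc number of functional concentrations (default 9).
#' @param func_step log10 step between functional concentrations (default
#'   0.5, i.e. half-log).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       cv_functional = 0.05, cv_binding = 0.03,
                       n_replicates_functional = 3,
                       n_replicates_binding = 4,
                       n_experiments = 3,
                       basal_range = c(0.02, 0.03),
                       incorporated_dpm = 2e5,
                       sat_conc = c(63, 125, 250, 500, 1000, 2000) * 1e-12,
                       radioligand_conc = 1e-9,
                       ns_slope = 0.005,
                       specific_activity = 80,
                       protein_mg = 0.01, volume_L = 8e-4,
                       func_n_conc = 9, func_step = 0.5) {
  stopifnot(length(basal_range) == 2, basal_range[1] <= basal_range[2],
            cv_functional >= 0, cv_binding >= 0, n_experiments >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# multiplicative Gaussian noise with coefficient of variation cv
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(x * (1 + stats::rnorm(length(x), 0, cv)), 0)
}

#' Simulate a saturation binding experiment
#'
#' Total and nonspecific binding (dpm) per replicate are generated from the
#' binding isotherm with depletion-consistent bookkeeping: specifically
#' bound ligand satisfies `bound = Rtot * free / (KD + free)` with
#' `free = added - bound` (solved exactly), so the analysis-side subtraction
#' `free = added - specific` recovers the generator's free concentrations.
#' Nonspecific binding is linear in added radioligand. The ground truth
#' (including per-point free concentrations) is attached as attribute
#' `"truth"`.
#'
#' @param config a [sim_config()].
#' @param pKD true radioligand pKD (-log10 molar).
#' @param BMAX true density of binding sites, pmol/mg protein.
#' @return A [saturation_series()] with attribute `truth`.
#' @export
simulate_saturation <- function(config, pKD = 9.6, BMAX = 2) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  KD <- 10^(-pKD)
  Rtot <- BMAX * 1e-12 * config$protein_mg / config$volume_L  # molar sites
  added <- config$sat_conc
  # bound solves bound^2 - (added + Rtot + KD) bound + added*Rtot = 0
  b <- added + Rtot + KD
  bound <- (b - sqrt(b^2 - 4 * added * Rtot)) / 2
  free <- added - bound
  ns <- config$ns_slope * added
  nrep <- config$n_replicates_binding
  tot_dpm <- molar_to_dpm(bound + ns, config$specific_activity,
                          config$volume_L)
  ns_dpm <- molar_to_dpm(ns, config$specific_activity, config$volume_L)
  total <- matrix(mult_noise(rep(tot_dpm, nrep), config$cv_binding),
                  ncol = nrep)
  nonspec <- matrix(mult_noise(rep(ns_dpm, nrep), config$cv_binding),
                    ncol = nrep)
  out <- saturation_series(added, total, nonspec,
                           specific_activity = config$specific_activity,
                           protein_mg = config$protein_mg,
                           volume_L = config$volume_L)
  attr(out, "truth") <- list(pKD = pKD, BMAX = BMAX, free = free,
                             bound = bound, nonspecific = ns)
  out
}

#' Simulate a competition binding experiment
#'
#' Percent-of-control displacement curves from the one- or two-site
#' competition model, with the competitor IC50(s) derived from true pKI
#' value(s) by the inverse Cheng-Prusoff relation at the configured
#' radioligand concentration.
#'
#' @param config a [sim_config()].
#' @param ligand competitor name.
#' @param pKI true pKI; length 1 for one site, length 2 (high, low) for two
#'   sites.
#' @param f_low percent of low-affinity sites (two-site truth only).
#' @param radioligand_pKD true radioligand pKD.
#' @param concentrations competitor concentrations; default 12 half-log
#'   points bracketing the IC50s.
#' @return A [conc_response_series()] (responses in percent of control) with
#'   attribute `truth`.
#' @export
simulate_competition <- function(config, ligand = "carbachol",
                                 pKI = 4.62, f_low = 50,
                                 radioligand_pKD = 9.6,
                                 concentrations = NULL) {
  stopifnot(inherits(config, "sim_config"), length(pKI) %in% 1:2)
  set.seed(config$seed + 1L)
  corr <- log10(1 + config$radioligand_conc / 10^(-radioligand_pKD))
  pIC50 <- pKI - corr  # IC50 = KI * (1 + [D]/KD)
  if (is.null(concentrations)) {
    lo <- min(pIC50); hi <- max(pIC50)
    concentrations <- 10^seq(-(hi + 3), -(lo - 2.5), by = 0.5)
  }
  x <- concentrations
  y <- if (length(pKI) == 1) {
    100 - 100 * x / (x + 10^(-pIC50))
  } else {
    100 - (100 - f_low) * x / (x + 10^(-pIC50[1])) -
      f_low * x / (x + 10^(-pIC50[2]))
  }
  nrep <- config$n_replicates_binding
  resp <- matrix(mult_noise(rep(y, nrep), config$cv_binding), ncol = nrep)
  out <- conc_response_series(x, resp, ligand = ligand, pathway = "binding",
                              response_unit = "pct_of_control")
  attr(out, "truth") <- list(pKI = pKI, pIC50 = pIC50, f_low = f_low,
                             model = if (length(pKI) == 1) "one_site"
                                     else "two_site",
                             radioligand_pKD = radioligand_pKD)
  out
}

#' Simulate functional concentration-response experiments
#'
#' Generates inositol-phosphate accumulation curves from the operational
#' model (rebased so basal response is 1). Per experiment, a basal dpm level
#' is drawn uniformly within the configured 2-3% band of incorporated
#' radioactivity; well-level dpm are the true fold-response times basal with
#' multiplicative noise, then re-expressed as fold over the experiment's
#' basal. A `"no response"` truth (`tau = 0` or `NULL` parameters) yields
#' flat curves at 1 plus noise.
#'
#' @param config a [sim_config()].
#' @param ligand agonist name.
#' @param system_emax,tau,pKA true operational parameters; `tau = 0` for a
#'   non-responding agonist.
#' @param receptor,variant,pathway construct labels for the series.
#' @param concentrations molar grid; default `func_n_conc` points in
#'   `func_step` log10 steps centred on the true pEC50 (or a generic
#'   nanomolar-to-millimolar window for flat truths).
#' @return A list of [conc_response_series()], one per experiment, with
#'   attribute `truth`.
#' @export
simulate_functional <- function(config, ligand = "carbachol",
                                system_emax = 30.7, tau = 1.41, pKA = 6.6,
                                receptor = "M2", variant = "fused",
                                pathway = "IPx", concentrations = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  flat <- is.null(tau) || tau <= 0
  if (is.null(concentrations)) {
    centre <- if (flat) 6 else pKA + log10(1 + tau)  # pEC50
    half <- (config$func_n_conc - 1) / 2
    concentrations <- 10^(-(centre + config$func_step * (half:(-half))))
  }
  x <- concentrations
  y_true <- if (flat) rep(1, length(x))
            else operational_response(x, system_emax, tau, pKA)
  nrep <- config$n_replicates_functional
  series <- vector("list", config$n_experiments)
  for (e in seq_len(config$n_experiments)) {
    basal_dpm <- stats::runif(1, config$basal_range[1],
                              config$basal_range[2]) * config$incorporated_dpm
    well_dpm <- mult_noise(rep(y_true * basal_dpm, nrep),
                           config$cv_functional)
    resp <- matrix(well_dpm / basal_dpm, ncol = nrep)
    series[[e]] <- conc_response_series(
      x, resp, receptor = receptor, variant = variant, pathway = pathway,
      ligand = ligand, experiment_id = sprintf("exp%d", e))
    attr(series[[e]], "basal_dpm") <- basal_dpm
  }
  attr(series, "truth") <- list(system_emax = system_emax,
                                tau = if (flat) 0 else tau,
                                pKA = if (flat) NA_real_ else pKA,
                                pEC50 = if (flat) NA_real_
                                        else pKA + log10(1 + tau),
                                emax_prime = if (flat) 1 else
                                  operational_to_hill(system_emax, tau,
                                                      pKA)$emax_prime)
  series
}

#' Simulate cAMP concentration-response experiments
#'
#' Wild-type M2/M4 receptors respond to agonist biphasically over a
#' forskolin-stimulated basal of 1: inhibition of cAMP synthesis through
#' preferential Gi/o at submicromolar concentrations, superimposed on
#' stimulation through non-preferential Gs at micromolar concentrations.
#' Galpha16-fused constructs are excluded from endogenous G-protein coupling
#' and give flat curves at 1.
#'
#' @param config a [sim_config()].
#' @param variant `"wt"` (biphasic) or `"fused"` (flat).
#' @param receptor receptor label.
#' @param ligand agonist name.
#' @param inhib_amplitude,pIC50 descending (Gi/o) component: amplitude as
#'   fraction of basal and its midpoint.
#' @param stim_amplitude,pEC50 ascending (Gs) component.
#' @param concentrations molar grid; default 11 half-log points from 10 nM
#'   to 1 mM.
#' @return A list of [conc_response_series()] (pathway `"cAMP"`), one per
#'   experiment, with attribute `truth`.
#' @export
simulate_camp <- function(config, variant = c("wt", "fused"),
                          receptor = "M2", ligand = "carbachol",
                          inhib_amplitude = 0.4, pIC50 = 7,
                          stim_amplitude = 0.6, pEC50 = 5,
                          concentrations = 10^seq(-8, -3, by = 0.5)) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  x <- concentrations
  y_true <- if (variant == "fused") rep(1, length(x)) else
    1 - inhib_amplitude * x / (x + 10^(-pIC50)) +
      stim_amplitude * x / (x + 10^(-pEC50))
  nrep <- config$n_replicates_functional
  series <- vector("list", config$n_experiments)
  for (e in seq_len(config$n_experiments)) {
    resp <- matrix(mult_noise(rep(y_true, nrep), config$cv_functional),
                   ncol = nrep)
    series[[e]] <- conc_response_series(
      x, resp, receptor = receptor, variant = variant, pathway = "cAMP",
      ligand = ligand, experiment_id = sprintf("exp%d", e))
  }
  attr(series, "truth") <- list(variant = variant, y_true = y_true,
                                inhib_amplitude = inhib_amplitude,
                                pIC50 = pIC50,
                                stim_amplitude = stim_amplitude,
                                pEC50 = pEC50)
  series
}
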