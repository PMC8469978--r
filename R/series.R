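#' Concentration-response series
#'
#' Container for replicate responses of one (receptor construct, ligand,
#' pathway) combination over a concentration range. Functional responses are
#' fold over basal (basal == 1); competition-binding responses are percent of
#' control radioligand binding.
#'
#' @param concentrations molar concentrations, strictly positive; sorted
#'   ascending on construction.
#' @param responses numeric matrix with one row per concentration and one
#'   column per replicate (NA allowed for missing wells), or a vector for a
#'   single replicate.
#' @param receptor receptor subtype label, e.g. `"M2"`.
#' @param variant construct variant: `"wt"`, `"fused"` or `"cotransfected"`.
#' @param pathway functional readout, e.g. `"IPx"`, `"cAMP"` or `"binding"`.
#' @param ligand ligand name.
#' @param experiment_id identifier of the independent experiment.
#' @param basal basal response level in response units (fold-over-basal data
#'   have basal 1 by construction).
#' @param response_unit unit label carried through I/O.
#' @return An object of class `conc_response_series`.
#' @export
conc_response_series <- function(concentrations, responses,
                                 receptor = "M2", variant = "fused",
                                 pathway = "IPx", ligand = "carbachol",
                                 experiment_id = "exp1",
                                 basal = 1, response_unit = "fold_over_basal") {
  if (is.vector(responses)) responses <- matrix(responses, ncol = 1)
  responses <- as.matrix(responses)
  if (length(concentrations) != nrow(responses))
    stop("responses must have one row per concentration")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("concentrations must be finite, strictly positive molar values")
  if (basal <= 0) stop("basal must be positive")
  if (any(responses < 0, na.rm = TRUE))
    stop("responses must be non-negative")
  ord <- order(concentrations)
  structure(
    list(concentrations = concentrations[ord],
         responses = responses[ord, , drop = FALSE],
         receptor = receptor, variant = variant, pathway = pathway,
         ligand = ligand, experiment_id = experiment_id,
         basal = basal, response_unit = response_unit),
    class = "conc_response_series")
}

#' @export
print.conc_response_series <- function(x, ...) {
  cat(sprintf("<conc_response_series> %s %s (%s), %s [%s]\n",
              x$receptor, x$variant, x$pathway, x$ligand, x$experiment_id))
  cat(sprintf("  %d concentrations (%.3g to %.3g M), %d replicate(s), unit %s\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), ncol(x$responses), x$response_unit))
  invisible(x)
}

# flatten to (x, y) pairs, dropping NA wells
series_xy <- function(series) {
  x <- rep(series$concentrations, ncol(series$responses))
  y <- as.vector(series$responses)
  keep <- !is.na(y)
  list(x = x[keep], y = y[keep])
}

#' Radioligand saturation binding series
#'
#' Raw total and nonspecific binding (dpm) at increasing added radioligand
#' concentrations, with the constants needed to convert counts to molar
#' concentrations and binding-site densities: the scintillation counting
#' efficiency (counts are divided by it to give dpm), the radioligand
#' specific activity, the incubation volume, and the membrane protein per
#' sample.
#'
#' @param added_conc added radioligand concentration per point, molar.
#' @param total_dpm,nonspecific_dpm matrices (points x replicates) of total
#'   and nonspecific binding in dpm.
#' @param specific_activity radioligand specific activity, Ci/mmol.
#' @param counting_efficiency fraction in (0, 1]; 1 when values are true dpm.
#' @param protein_mg membrane protein per sample, mg.
#' @param volume_L incubation volume, litres.
#' @return An object of class `saturation_series`.
#' @export
saturation_series <- function(added_conc, total_dpm, nonspecific_dpm,
                              specific_activity = 80,
                              counting_efficiency = 1,
                              protein_mg = 0.01, volume_L = 8e-4) {
  if (is.vector(total_dpm)) total_dpm <- matrix(total_dpm, ncol = 1)
  if (is.vector(nonspecific_dpm)) nonspecific_dpm <- matrix(nonspecific_dpm, ncol = 1)
  total_dpm <- as.matrix(total_dpm); nonspecific_dpm <- as.matrix(nonspecific_dpm)
  if (length(added_conc) != nrow(total_dpm) ||
      length(added_conc) != nrow(nonspecific_dpm))
    stop("dpm matrices must have one row per added concentration")
  if (any(added_conc <= 0)) stop("added concentrations must be positive")
  if (counting_efficiency <= 0 || counting_efficiency > 1)
    stop("counting_efficiency must be in (0, 1]")
  ord <- order(added_conc)
  structure(
    list(added_conc = added_conc[ord],
         total_dpm = total_dpm[ord, , drop = FALSE],
         nonspecific_dpm = nonspecific_dpm[ord, , drop = FALSE],
         specific_activity = specific_activity,
         counting_efficiency = counting_efficiency,
         protein_mg = protein_mg, volume_L = volume_L),
    class = "saturation_series")
}

#' @export
print.saturation_series <- function(x, ...) {
  cat(sprintf("<saturation_series> %d concentrations (%.0f to %.0f pM), %d replicate(s)\n",
              length(x$added_conc), min(x$added_conc) * 1e12,
              max(x$added_conc) * 1e12, ncol(x$total_dpm)))
  invisible(x)
}

# dpm -> molar concentration in the incubation volume.
# 1 Ci = 2.22e12 dpm; specific activity in Ci/mmol.
dpm_to_molar <- function(dpm, specific_activity, volume_L,
                         counting_efficiency = 1) {
  mmol <- (dpm / counting_efficiency) / (2.22e12 * specific_activity)
  (mmol * 1e-3) / volume_L
}

molar_to_dpm <- function(conc, specific_activity, volume_L,
                         counting_efficiency = 1) {
  mmol <- conc * volume_L * 1e3
  mmol * 2.22e12 * specific_activity * counting_efficiency
}
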