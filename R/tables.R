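# Bundled reference parameter sets for muscarinic receptor-Galpha16 fusion
# pharmacology: operational-model parameters (tau, pKA), relative intrinsic
# activities and binding affinities measured in CHO cells. They serve as
# realistic ground truths for the simulator, as worked-example inputs, and as
# the desk-scale inputs for closed-form consistency checks.

#' Reference operational parameters for the Galpha16-fused receptor panel
#'
#' Per (receptor, ligand) operational efficacy `tau`, operational affinity
#' `pKA` and relative intrinsic activity `RAi` (reference agonist carbachol)
#' for the five muscarinic receptor subtypes fused to Galpha16, measured as
#' inositol-phosphate accumulation in CHO cells (means and SDs over three
#' independent experiments in triplicate). `tau = 0` rows mark agonists that
#' do not stimulate the pathway (`pKA` not calculated).
#'
#' @return A data.frame with columns `receptor`, `ligand`, `tau`, `tau_sd`,
#'   `pKA`, `pKA_sd`, `RAi`, `RAi_sd`.
#' @export
ref_fused_params <- function() {
  lig <- c("arecoline", "carbachol", "furmethide", "iperoxo", "McN-A-343",
           "NDMC", "oxotremorine", "pilocarpine", "xanomeline", "JR6", "JR7")
  mk <- function(receptor, tau, tau_sd, pKA, pKA_sd, RAi, RAi_sd)
    data.frame(receptor = receptor, ligand = lig,
               tau = tau, tau_sd = tau_sd, pKA = pKA, pKA_sd = pKA_sd,
               RAi = RAi, RAi_sd = RAi_sd)
  rbind(
    mk("M1",
       c(0.594, 0.887, 0.655, 1.577, 0.472, 0.500, 0.869, 0.668, 0.795, 0, 0),
       c(0.057, 0.017, 0.005, 0.055, 0.020, 0.009, 0.027, 0.040, 0.007, 0, 0),
       c(6.68, 6.80, 6.30, 8.24, 6.53, 7.43, 7.82, 6.29, 8.25, NA, NA),
       c(0.01, 0.06, 0.03, 0.03, 0.10, 0.05, 0.05, 0.02, 0.02, NA, NA),
       c(0.45, 1, 0.234, 45.9, 0.248, 2.40, 10.3, 0.234, 25.0, 0, 0),
       c(0.025, 0.01, 0.001, 0.9, 0.006, 0.02, 0.2, 0.008, 0.1, 0, 0)),
    mk("M2",
       c(1.566, 1.410, 1.669, 9.610, 1.033, 0.951, 2.799, 0.946, 1.669, 0, 0),
       c(0.038, 0.028, 0.034, 0.227, 0.021, 0.016, 0.081, 0.020, 0.034, 0, 0),
       c(6.73, 6.60, 6.18, 7.62, 6.68, 6.70, 7.64, 6.39, 8.15, NA, NA),
       c(0.06, 0.06, 0.03, 0.08, 0.04, 0.02, 0.08, 0.02, 0.03, NA, NA),
       c(1.47, 1, 0.446, 71.3, 0.875, 0.846, 21.4, 0.407, 41.9, 0, 0),
       c(0.02, 0.01, 0.005, 1, 0.010, 0.008, 0.4, 0.005, 0.5, 0, 0)),
    mk("M3",
       c(0.541, 0.918, 0.656, 2.926, 0.307, 0.497, 0.834, 0.697, 0.777, 0, 0),
       c(0.004, 0.020, 0.009, 0.876, 0.046, 0.003, 0.027, 0.039, 0.022, 0, 0),
       c(7.10, 6.80, 5.95, 8.56, 5.81, 7.43, 7.84, 6.31, 8.25, NA, NA),
       c(0.01, 0.08, 0.31, 0.10, 0.13, 0.06, 0.05, 0.01, 0.03, NA, NA),
       c(1.05, 1, 0.102, 176, 0.028, 2.35, 10.0, 0.247, 23.8, 0, 0),
       c(0, 0.01, 0.001, 30, 0.002, 0.01, 0.2, 0.008, 0.4, 0, 0)),
    mk("M4",
       c(0.804, 0.897, 0.865, 1.273, 0.704, 0.623, 0.994, 0.557, 0.866, 0, 0),
       c(0.071, 0.040, 0.084, 0.055, 0.070, 0.050, 0.049, 0.054, 0.084, 0, 0),
       c(7.19, 7.10, 6.64, 7.87, 6.93, 6.80, 7.95, 6.47, 8.59, NA, NA),
       c(0.04, 0.01, 0.01, 0.03, 0.02, 0.02, 0.01, 0.01, 0.01, NA, NA),
       c(1.11, 1, 0.330, 8.26, 0.523, 0.346, 7.76, 0.144, 29.6, 0, 0),
       c(0.06, 0.03, 0.018, 0.21, 0.030, 0.016, 0.22, 0.008, 1.7, 0, 0)),
    mk("M5",
       c(0.510, 1.126, 1.072, 0.825, 0.358, 0.709, 1.555, 0.800, 1.172, 0, 0),
       c(0.005, 0.015, 0.010, 0.031, 0.009, 0.009, 0.016, 0.023, 0.015, 0, 0),
       c(7.02, 6.70, 6.25, 8.46, 6.96, 7.07, 7.72, 6.34, 8.20, NA, NA),
       c(0.14, 0.02, 0.03, 0.14, 0.11, 0.03, 0.03, 0.01, 0.01, NA, NA),
       c(0.76, 1, 0.336, 35.0, 0.452, 1.47, 14.5, 0.309, 33.0, 0, 0),
       c(0.005, 0.01, 0.002, 1, 0.006, 0.01, 0.1, 0.005, 0.2, 0, 0)))
}

#' Reference system maximal responses for the fused receptor panel
#'
#' @return Named numeric vector of system E_MAX (fold over basal) per fused
#'   receptor subtype, with SDs as the `"sd"` attribute.
#' @export
ref_system_emax <- function() {
  e <- c(M1 = 27.1, M2 = 30.7, M3 = 27.1, M4 = 27.1, M5 = 28.9)
  attr(e, "sd") <- c(M1 = 0.5, M2 = 0.603, M3 = 0.6, M4 = 1.2, M5 = 0.4)
  e
}

#' Reference functional parameters for M2 and M5 receptor variants
#'
#' Hill and operational parameters of carbachol, oxotremorine and iperoxo
#' responses (inositol-phosphate accumulation) at wild-type, Galpha16
#' co-transfected, and Galpha16-fused M2 and M5 receptors, together with the
#' per-construct system maximum. `construct` combines receptor and variant
#' (`"M2_Ga16"` fused, `"M2+Ga16"` co-transfected, `"M2_wt"` wild type).
#'
#' @return A data.frame with columns `construct`, `receptor`, `variant`,
#'   `ligand`, `pEC50`, `pEC50_sd`, `emax_prime`, `emax_prime_sd`, `tau`,
#'   `tau_sd`, `pKA`, `pKA_sd`, `RAi`, `RAi_sd`, `system_emax`,
#'   `system_emax_sd`.
#' @export
ref_variant_params <- function() {
  row <- function(construct, receptor, variant, ligand, pec, pec_sd,
                  em, em_sd, tau, tau_sd, pka, pka_sd, rai, rai_sd,
                  semax, semax_sd)
    data.frame(construct = construct, receptor = receptor, variant = variant,
               ligand = ligand, pEC50 = pec, pEC50_sd = pec_sd,
               emax_prime = em, emax_prime_sd = em_sd,
               tau = tau, tau_sd = tau_sd, pKA = pka, pKA_sd = pka_sd,
               RAi = rai, RAi_sd = rai_sd,
               system_emax = semax, system_emax_sd = semax_sd)
  rbind(
    row("M2+Ga16", "M2", "cotransfected", "carbachol",
        5.59, 0.12, 4.62, 0.37, 0.88, 0.17, 5.52, 0.17, 1, 0.03, 5.8, 0.4),
    row("M2+Ga16", "M2", "cotransfected", "oxotremorine",
        6.53, 0.13, 4.46, 0.33, 0.85, 0.15, 6.26, 0.10, 5.41, 0.05, 5.8, 0.4),
    row("M2_Ga16", "M2", "fused", "carbachol",
        6.99, 0.06, 18.0, 0.4, 1.41, 0.03, 6.60, 0.06, 1, 0.01, 30.7, 0.603),
    row("M2_Ga16", "M2", "fused", "oxotremorine",
        8.22, 0.08, 22.4, 0.6, 2.80, 0.08, 7.64, 0.08, 21.4, 0.4, 30.7, 0.603),
    row("M2_wt", "M2", "wt", "carbachol",
        6.01, 0.04, 1.91, 0.07, 0.20, 0.10, 5.90, 0.10, 1, 0.01, 5.5, 0.4),
    row("M2_wt", "M2", "wt", "oxotremorine",
        6.68, 0.05, 1.60, 0.05, 0.20, 0.10, 6.60, 0.10, 3.08, 0.28, 5.5, 0.4),
    row("M5+Ga16", "M5", "cotransfected", "carbachol",
        6.61, 0.08, 11.7, 0.4, 0.814, 0.030, 6.35, 0.08, 1, 0.02, 21, NA),
    row("M5+Ga16", "M5", "cotransfected", "iperoxo",
        8.95, 0.14, 11.4, 0.8, 0.785, 0.057, 8.70, 0.14, 213, 9, 21, NA),
    row("M5_Ga16", "M5", "fused", "carbachol",
        7.03, 0.02, 15.3, 0.2, 1.126, 0.015, 6.70, 0.02, 1, 0.01, 29, 3),
    row("M5_Ga16", "M5", "fused", "iperoxo",
        8.72, 0.14, 11.3, 0.4, 0.825, 0.031, 8.46, 0.14, 35, 1, 29, 3),
    row("M5_wt", "M5", "wt", "carbachol",
        6.09, 0.16, 10.1, 1.1, 0.68, 0.077, 5.86, 0.16, 1, 0.06, 22, 2),
    row("M5_wt", "M5", "wt", "iperoxo",
        8.93, 0.16, 13.0, 1.1, 1.08, 0.09, 8.61, 0.16, 912, 45, 22, 2))
}

#' Reference agonist binding affinities at Galpha16-fused receptors
#'
#' Cheng-Prusoff-corrected inhibition constants (negative log10 molar pKI)
#' of muscarinic agonists competing with 1 nM radiolabelled
#' N-methylscopolamine at the fused receptor panel. Most agonists show a
#' single (low-affinity) site; iperoxo at M1 and JR6 at M4 additionally show
#' a high-affinity site.
#'
#' @return A data.frame with columns `receptor`, `ligand`, `site`
#'   (`"high"`/`"low"`), `pKI`, `pKI_sd`.
#' @export
ref_binding_affinities <- function() {
  long <- function(ligand, site, pKI, pKI_sd)
    data.frame(receptor = c("M1", "M2", "M3", "M4", "M5"), ligand = ligand,
               site = site, pKI = pKI, pKI_sd = pKI_sd)
  rbind(
    long("arecoline", "low", c(5.19, 4.68, 5.17, 4.68, 5.16),
         c(0.06, 0.03, 0.08, 0.01, 0.04)),
    long("carbachol", "low", c(4.87, 4.62, 4.77, 4.61, 4.72),
         c(0.01, 0.01, 0.02, 0.02, 0.01)),
    long("furmethide", "low", c(5.79, 4.69, 5.27, 4.71, 5.25),
         c(0.01, 0.04, 0.03, 0.01, 0.02)),
    data.frame(receptor = "M1", ligand = "iperoxo", site = "high",
               pKI = 8.35, pKI_sd = 0.12),
    long("iperoxo", "low", c(6.20, 5.83, 6.06, 5.96, 6.99),
         c(0.08, 0.03, 0.04, 0.03, 0.02)),
    long("McN-A-343", "low", c(4.24, 6.54, 5.14, 6.41, 5.34),
         c(0.04, 0.04, 0.02, 0.02, 0.06)),
    long("NDMC", "low", c(7.06, 6.51, 6.75, 6.40, 6.77),
         c(0.01, 0.04, 0.02, 0.01, 0.03)),
    long("oxotremorine", "low", c(6.61, 5.70, 6.24, 5.86, 6.16),
         c(0.01, 0.04, 0.03, 0.02, 0.03)),
    long("pilocarpine", "low", c(5.26, 4.52, 4.92, 4.54, 4.88),
         c(0.02, 0.01, 0.02, 0.03, 0.04)),
    long("xanomeline", "low", c(7.29, 6.82, 7.19, 7.04, 7.06),
         c(0.01, 0.02, 0.04, 0.03, 0.02)),
    data.frame(receptor = "M4", ligand = "JR6", site = "high",
               pKI = 6.73, pKI_sd = 0.28),
    long("JR6", "low", c(4.97, 5.74, 5.07, 5.29, 5.44),
         c(0.07, 0.10, 0.04, 0.21, 0.05)),
    long("JR7", "low", c(4.34, 5.17, 4.22, 4.82, 4.46),
         c(0.05, 0.07, 0.06, 0.03, 0.04)))
}
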