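# Shared study conditions for the analysis scripts.
#
# Desk-scale system preserving the modeled nucleus's ratios: chains span
# the cavity (contour/box ~ 1.2) at comparable envelope grafting density
# and monomer volume fraction, with a rigidity grid from the flexible to
# the stiff regime (relative to the cavity size).

library(scpolymer)

RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, showWarnings = FALSE)

study_conditions <- function(seed = 1L, n_target = 400L)
  experiment_config(
    kappas = c(1, 4, 12),
    tether_modes = c("two_tethers", "untethered"),
    n_chains = 4L, n_monomers = 24L, box_side = 53L,
    pilot_sweeps = 500000L, n_target = n_target,
    resample_n = 24L, n_bins = 24L, seed = seed)

# synthetic stand-in for reconstructed trace data: 19 SCs of ~12 um mean
# contour with envelope-tethered ends in a 10 um spherical nucleus
synthetic_nucleus_config <- function(seed, l_p_um = 2, noise_sigma_um = 0.05)
  synth_config(n_chains = 19L, contour_length_um = 12, n_points = 61L,
               l_p_um = l_p_um,
               cavity = list(shape = "sphere", diameter_um = 10),
               tether_mode = "two_tethers",
               noise_sigma_um = noise_sigma_um, seed = seed)
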