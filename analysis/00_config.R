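# Shared settings for the analysis scripts. Every script can be run on its
# own from the repository root: each reads what it needs from results/data
# (written by 01_simulate_cohorts.R) and writes its outputs under results/.

library(gcimptrace)

DATA_DIR <- "results/data"
OUT_DIR <- "results"
SEED <- 2018

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

# study conditions: a 7-subtype reference cohort for training, and a
# longitudinal G-CIMP-high cohort of 53 patients with the observed
# transition mix (9 change, 7 intermediate, 37 retain)
# archetype separation 0.6 in both cohorts: large enough that the
# asymmetric delta-beta preset (0.5 / -0.4) is attainable, and matched
# between training and application so the intermediate index windows
# retain their meaning
reference_config <- function() cohort_config(
  n_patients_per_subtype = 20, signature_effect = 0.6,
  noise_concentration = 50, seed = SEED)

longitudinal_config <- function() cohort_config(
  n_patients_per_subtype = c(gcimp_high = 53, codel = 6, gcimp_low = 6,
                             classic_like = 4, mesenchymal_like = 4,
                             lgm6_gbm = 2, pa_like = 2),
  fraction_change = 9 / 53, fraction_intermediate = 7 / 53,
  signature_effect = 0.6, noise_concentration = 50,
  fragments_per_surgery = 2, seed = SEED + 1)

data_path <- function(...) file.path(DATA_DIR, ...)
out_path <- function(...) file.path(OUT_DIR, ...)
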