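# Shared synthetic cohorts and a trained classifier, built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

ref_cohort <- function() memo("ref", generate_reference_cohort(
  cohort_config(n_patients_per_subtype = 8, seed = 42)))

truth_labels <- function(cohort)
  setNames(cohort$truth$subtype, cohort$truth$sample_id)

ref_model <- function() memo("model", {
  r <- ref_cohort()
  train_subtype_classifier(r$beta, truth_labels(r), r$signatures,
                           n_trees = 200, seed = 1)
})

long_cohort <- function() memo("long", generate_longitudinal_cohort(
  cohort_config(n_patients_per_subtype = c(gcimp_high = 53),
                fraction_change = 9 / 53, fraction_intermediate = 7 / 53,
                seed = 7)))

# a cohort strong enough that the asymmetric 0.5/-0.4 preset applies
long_cohort_strong <- function() memo("long_strong",
  generate_longitudinal_cohort(
    cohort_config(n_patients_per_subtype = c(gcimp_high = 24),
                  fraction_change = 9 / 24, signature_effect = 0.6,
                  seed = 11)))
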