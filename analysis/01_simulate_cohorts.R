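#!/usr/bin/env Rscript
# Generate the synthetic study cohorts and write every table downstream
# steps consume: beta matrices, sample sheets, probe annotation, signature
# probe lists, and the planted ground truth.

source("analysis/00_config.R")

ref <- generate_reference_cohort(reference_config())
lng <- generate_longitudinal_cohort(longitudinal_config())

write_beta_matrix(ref$beta, data_path("reference_beta.tsv"))
write_table_tsv(ref$sheet, data_path("reference_sheet.tsv"))
write_table_tsv(ref$truth, data_path("reference_truth.tsv"))

write_beta_matrix(lng$beta, data_path("longitudinal_beta.tsv"))
write_table_tsv(lng$sheet, data_path("longitudinal_sheet.tsv"))
write_table_tsv(lng$annotation, data_path("longitudinal_annotation.tsv"))
write_table_tsv(lng$truth, data_path("longitudinal_truth.tsv"))

for (sig in lng$signatures)
  write_signature_set(sig, data_path(paste0("signature_", sig$name, ".txt")))

write_run_summary(list(
  reference_samples = ncol(ref$beta),
  longitudinal_samples = ncol(lng$beta),
  longitudinal_patients = length(unique(lng$sheet$patient_id)),
  planted_transitions = as.list(table(lng$truth$category)),
  probes = nrow(lng$beta)), data_path("simulation_summary.json"))

cat(sprintf(paste0(
  "simulated %d reference samples (7 subtypes x 20 patients) and %d\n",
  "longitudinal fragments from %d patients (planted: %d change, %d\n",
  "intermediate, %d no-change among the 53 G-CIMP-high patients)\n"),
  ncol(ref$beta), ncol(lng$beta), length(unique(lng$sheet$patient_id)),
  sum(lng$truth$category == "change"),
  sum(lng$truth$category == "intermediate_change"),
  sum(lng$truth$category == "no_change" & lng$truth$subtype == "gcimp_high")))
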