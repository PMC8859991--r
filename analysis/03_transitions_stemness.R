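#!/usr/bin/env Rscript
# Aggregate fragment classifications to patient-timepoint labels, tabulate
# primary -> recurrence transitions, and score stemness (mDNAsi) with the
# G-CIMP-low-recurrence vs G-CIMP-high-primary comparison.

source("analysis/00_config.R")

sheet <- read_sample_sheet(data_path("longitudinal_sheet.tsv"))
res <- read.delim(out_path("classification_results.tsv"))
truth <- read.delim(data_path("longitudinal_truth.tsv"))

tt <- build_transition_table(sheet, res)
write_table_tsv(tt$table, out_path("transition_table.tsv"))
summ <- transition_summary(tt)
write_table_tsv(summ, out_path("transition_summary.tsv"))
cat("transitions among G-CIMP-high primaries:\n")
print(summ, row.names = FALSE)
agree <- mean(tt$table$category ==
              truth$category[match(tt$table$patient_id, truth$patient_id)])
cat(sprintf("agreement with planted transition truth: %.3f\n\n", agree))

beta <- read_beta_matrix(data_path("longitudinal_beta.tsv"))
stem <- read_signature_set(data_path("signature_stemness_219.txt"),
                           "stemness_219")
sc <- compute_mdnasi(beta, stem, sheet)
write_table_tsv(sc$scores, out_path("stemness_scores.tsv"))
write_table_tsv(sc$surgery_means, out_path("stemness_surgery_means.tsv"))

# G-CIMP-low recurrences vs the G-CIMP-high primary counterpart group
ch <- truth$patient_id[truth$category == "change"]
hi <- truth$patient_id[truth$subtype == "gcimp_high"]
grp <- setNames(rep(NA_character_, nrow(sheet)), sheet$sample_id)
grp[sheet$sample_id[sheet$patient_id %in% hi &
                    sheet$timepoint == "primary"]] <- "gcimp_high_primary"
grp[sheet$sample_id[sheet$patient_id %in% ch &
                    sheet$timepoint == "first_recurrence"]] <- "gcimp_low_recurrence"
cmp <- compare_stemness_groups(sc$scores, grp[!is.na(grp)])
cat(sprintf("mDNAsi medians %s=%.3f vs %s=%.3f, rank-sum p = %.2e\n",
            cmp$groups[1], cmp$median[1], cmp$groups[2], cmp$median[2],
            cmp$p_value))
write_run_summary(list(groups = cmp$groups, n = cmp$n, median = cmp$median,
                       p_value = cmp$p_value),
                  out_path("stemness_comparison.json"))
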