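#!/usr/bin/env Rscript
# Supervised differential methylation of the transitioning pairs: compare
# the G-CIMP-high primaries of "change" patients (reference, group A)
# against their G-CIMP-low first recurrences (case, group B) with the
# rank-sum + BH + asymmetric delta-beta filter, and check recovery of the
# planted hypo/hyper probe sets.

source("analysis/00_config.R")

beta <- read_beta_matrix(data_path("longitudinal_beta.tsv"))
sheet <- read_sample_sheet(data_path("longitudinal_sheet.tsv"))
truth <- read.delim(data_path("longitudinal_truth.tsv"))
sig163 <- read_signature_set(data_path("signature_idh_mut_subtype_163.txt"),
                             "idh_mut_subtype_163")

ch <- truth$patient_id[truth$category == "change"]
groupA <- sheet$sample_id[sheet$patient_id %in% ch &
                          sheet$timepoint == "primary"]
groupB <- sheet$sample_id[sheet$patient_id %in% ch &
                          sheet$timepoint == "first_recurrence"]
cat(sprintf("comparing %d primary vs %d recurrent fragments of %d change patients\n",
            length(groupA), length(groupB), length(ch)))

dmp <- wilcoxon_dmp(beta, groupA, groupB)
write_table_tsv(dmp, out_path("dmp_table.tsv"))

filt <- filter_dmps(dmp, dmp_preset("change_pair_712"))
write_table_tsv(filt, out_path("dmp_filtered.tsv"))
counts <- attr(filt, "counts")
cat(sprintf("FDR < 0.05 with delta > 0.5 / < -0.4: %d hypo, %d hyper\n",
            counts["hypo"], counts["hyper"]))

hypo_rec <- mean(sig163$probe_ids %in% filt$probe_id[filt$direction == "hypo"])
hyper_planted <- grep("^hyp", rownames(beta), value = TRUE)
hyper_rec <- mean(hyper_planted %in% filt$probe_id[filt$direction == "hyper"])
cat(sprintf("planted recovery: hypo %.3f, hyper %.3f\n", hypo_rec, hyper_rec))

write_run_summary(list(n_hypo = unname(counts["hypo"]),
                       n_hyper = unname(counts["hyper"]),
                       hypo_recovery = hypo_rec,
                       hyper_recovery = hyper_rec),
                  out_path("dmp_summary.json"))
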