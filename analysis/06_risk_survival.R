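#!/usr/bin/env Rscript
# Apply the 7-CpG recurrence-risk panel to primary fragments, validate the
# calls against the planted transition truth, and stratify survival
# (Kaplan-Meier, log-rank, Cox hazard ratio).

source("analysis/00_config.R")

beta <- read_beta_matrix(data_path("longitudinal_beta.tsv"))
sheet <- read_sample_sheet(data_path("longitudinal_sheet.tsv"))
truth <- read.delim(data_path("longitudinal_truth.tsv"))

# one primary fragment per patient carries the panel decision
primaries <- sheet$sample_id[sheet$timepoint == "primary" &
                             sheet$fragment_index == 1]
pred <- predict_risk_group(beta[, primaries])
pred$patient_id <- sheet$patient_id[match(pred$sample_id, sheet$sample_id)]
write_table_tsv(pred, out_path("risk_predictions.tsv"))

tl <- setNames(truth$risk_group[match(pred$patient_id, truth$patient_id)]
               == "risk", pred$sample_id)
val <- validate_panel(pred, tl)
cat("risk-call vs planted transition truth:\n")
print(val$table)
cat(sprintf("Fisher p = %.3g, OR = %.1f (%.1f-%.1f)\n",
            val$p_value, val$odds_ratio, val$ci[1], val$ci[2]))
cat(sprintf("risk fraction %.1f%%, capture of transitioning patients %.0f%%\n",
            100 * val$risk_fraction, 100 * val$capture_rate))

grp <- setNames(pred$risk_group, pred$patient_id)
grp <- grp[grp != "unevaluable"]
surv <- km_logrank(sheet, grp)
write_table_tsv(surv$km, out_path("km_curves.tsv"))
cat(sprintf("\nlog-rank chisq = %.2f (p = %.3g); Cox HR = %.2f (95%% CI %.2f-%.2f)\n",
            surv$logrank_chisq, surv$logrank_p, surv$hazard_ratio,
            surv$hr_ci[1], surv$hr_ci[2]))
write_run_summary(list(
  fisher_p = val$p_value, odds_ratio = val$odds_ratio,
  risk_fraction = val$risk_fraction, capture_rate = val$capture_rate,
  logrank_p = surv$logrank_p, hazard_ratio = surv$hazard_ratio,
  hr_ci = surv$hr_ci, n = surv$n, events = surv$events),
  out_path("risk_survival_summary.json"))
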