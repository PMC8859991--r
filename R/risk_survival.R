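# The 7-CpG recurrence-risk predictor and survival stratification:
# per-probe beta dichotomization at the published cutoffs, the n >= 5 risk
# rule, panel validation by Fisher's exact test, and Kaplan-Meier /
# log-rank / Cox hazard-ratio comparison of the risk groups.

#' The 7-CpG biomarker panel with its published beta cutoffs
#'
#' A sample is concordant at a probe when its beta value lies strictly
#' below the probe's cutoff (the panel probes are hypomethylated in
#' G-CIMP-high primaries that later progress); the risk call requires
#' concordance at `min_probes_for_call` (5) of the 7 probes.
#'
#' @param direction per-probe concordance direction, `"below"` (default)
#'   or `"above"`, recycled over probes
#' @return data.frame of class `biomarker_panel`: probe_id, cutoff,
#'   direction; attribute `min_probes_for_call`
#' @export
biomarker_panel <- function(direction = "below") {
  panel <- data.frame(
    probe_id = c("cg09732711", "cg09326832", "cg24665265", "cg06220958",
                 "cg10245915", "cg11689625", "cg11799650"),
    cutoff = c(0.70, 0.28, 0.67, 0.17, 0.12, 0.31, 0.49),
    direction = rep(direction, length.out = 7),
    stringsAsFactors = FALSE)
  attr(panel, "min_probes_for_call") <- 5L
  class(panel) <- c("biomarker_panel", "data.frame")
  panel
}

panel_min_call <- function(panel) {
  attr(panel, "min_probes_for_call") %||% 5L
}

#' Dichotomize a sample's panel probes at their beta cutoffs
#'
#' Concordant iff beta < cutoff (strict; values at the cutoff are
#' non-concordant) for direction `"below"`, beta > cutoff for `"above"`.
#' Missing panel probes are excluded and counted.
#'
#' @param betas named numeric vector of beta values for one sample
#' @param panel a [biomarker_panel()]
#' @return logical vector named by panel probe (NA where unevaluable)
#' @export
dichotomize_probes <- function(betas, panel = biomarker_panel()) {
  b <- betas[panel$probe_id]
  conc <- ifelse(panel$direction == "below", b < panel$cutoff,
                 b > panel$cutoff)
  setNames(as.logical(conc), panel$probe_id)
}

#' Risk-group call for one or many samples
#'
#' Risk iff concordant at `min_probes_for_call` (default 5) or more panel
#' probes; `unevaluable` when fewer than that many probes have non-missing
#' beta values.
#'
#' @param beta beta matrix (or named vector for a single sample)
#' @param panel a [biomarker_panel()]
#' @return data.frame: sample_id, n_evaluable, n_concordant, risk_group
#'   (`risk` / `non_risk` / `unevaluable`)
#' @export
predict_risk_group <- function(beta, panel = biomarker_panel()) {
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1,
                                         dimnames = list(names(beta), "sample"))
  min_call <- panel_min_call(panel)
  res <- lapply(seq_len(ncol(beta)), function(j) {
    conc <- dichotomize_probes(beta[, j], panel)
    n_eval <- sum(!is.na(conc))
    n_conc <- sum(conc, na.rm = TRUE)
    grp <- if (n_eval < min_call) "unevaluable"
           else if (n_conc >= min_call) "risk" else "non_risk"
    data.frame(sample_id = colnames(beta)[j], n_evaluable = n_eval,
               n_concordant = n_conc, risk_group = grp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Validate the panel against an external binary truth label
#'
#' Cross-tabulates the risk call against the truth labels and reports the
#' two-sided Fisher exact p, the sample odds ratio with its Woolf 95% CI,
#' the capture rate (fraction of truth-positive samples called risk) and
#' the overall risk fraction. Unevaluable samples are excluded.
#'
#' @param predictions output of [predict_risk_group()]
#' @param truth named logical/character vector (names = sample IDs); TRUE /
#'   `"positive"` marks the class the panel should capture
#' @return list: `table` (2x2), `p_value`, `odds_ratio`, `ci`,
#'   `capture_rate`, `risk_fraction`, `n`
#' @export
validate_panel <- function(predictions, truth) {
  pred <- predictions[predictions$risk_group != "unevaluable", ]
  tv <- truth[pred$sample_id]
  if (anyNA(tv)) stop("truth labels missing for some samples")
  if (is.character(tv)) tv <- tv == "positive" | tv == "TRUE"
  risk <- pred$risk_group == "risk"
  a <- sum(risk & tv); b <- sum(risk & !tv)
  c_ <- sum(!risk & tv); d <- sum(!risk & !tv)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(risk = c("risk", "non_risk"),
                                truth = c("positive", "negative")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  orr <- if (degenerate)
    data.frame(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  else odds_ratio_ci(a, b, c_, d, feature = "panel")
  list(table = tab, p_value = p, odds_ratio = orr$odds_ratio,
       ci = c(orr$ci_low, orr$ci_high),
       capture_rate = if (a + c_ > 0) a / (a + c_) else NA_real_,
       risk_fraction = (a + b) / nrow(pred), n = nrow(pred))
}

#' Kaplan-Meier curves, log-rank test and hazard ratio between risk groups
#'
#' Product-limit estimates with right censoring per group, the two-group
#' log-rank test, and the hazard ratio of the second factor level vs the
#' first from a single-covariate Cox proportional-hazards fit (normal
#' approximation CI on the log HR). `hr_method = "logrank"` instead derives
#' the HR from the log-rank observed/expected event ratios.
#'
#' @param sheet sample sheet with `survival_time` and `survival_event`
#'   (one row per subject is used; duplicated patient IDs collapse to their
#'   first row)
#' @param groups named character vector (names = patient IDs) with two
#'   levels, e.g. risk / non_risk
#' @param hr_method `"cox"` (default) or `"logrank"`
#' @return list: `km` (data.frame time, n_risk, survival, group),
#'   `logrank_chisq`, `logrank_p`, `hazard_ratio`, `hr_ci`, `n`, `events`
#' @export
km_logrank <- function(sheet, groups, hr_method = c("cox", "logrank")) {
  hr_method <- match.arg(hr_method)
  sub <- sheet[!duplicated(sheet$patient_id), ]
  g <- groups[sub$patient_id]
  keep <- !is.na(g) & !is.na(sub$survival_time) & !is.na(sub$survival_event)
  sub <- sub[keep, ]
  g <- factor(g[keep])
  if (nlevels(g) < 2) stop("need two non-empty groups")
  if (any(table(g) == 0)) stop("empty group")
  if (sum(sub$survival_event) < 1) stop("no events observed")
  s <- survival::Surv(sub$survival_time, sub$survival_event)
  fit <- survival::survfit(s ~ g)
  km <- data.frame(time = fit$time, n_risk = fit$n.risk,
                   survival = fit$surv,
                   group = rep(levels(g), fit$strata))
  sd <- survival::survdiff(s ~ g)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = nlevels(g) - 1, lower.tail = FALSE)
  if (hr_method == "cox") {
    cx <- survival::coxph(s ~ g)
    hr <- unname(exp(stats::coef(cx)))
    se <- sqrt(diag(cx$var))[1]
    ci <- exp(stats::coef(cx)[1] + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    # observed/expected ratio of group 2 over group 1
    oe <- (sd$obs / sd$exp)
    hr <- unname(oe[2] / oe[1])
    se <- sqrt(sum(1 / sd$exp))
    ci <- exp(log(hr) + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  list(km = km, logrank_chisq = chisq, logrank_p = p,
       hazard_ratio = hr, hr_ci = unname(ci),
       n = as.integer(table(g)), events = sum(sub$survival_event))
}
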