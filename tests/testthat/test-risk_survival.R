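panel_betas <- function(values, panel = biomarker_panel()) {
  setNames(values, panel$probe_id)
}

test_that("dichotomization is strict-below with missing probes counted", {
  panel <- biomarker_panel()
  b <- panel_betas(c(0.65, 0.30, 0.60, 0.10, 0.05, 0.40, 0.49))
  conc <- dichotomize_probes(b, panel)
  # cg09732711 at 0.65 < 0.70 concordant; cg11799650 exactly at 0.49 is not
  expect_true(conc[["cg09732711"]])
  expect_false(conc[["cg11799650"]])
  expect_equal(sum(conc), 4)
  expect_equal(sum(dichotomize_probes(panel_betas(rep(0.99, 7)), panel)), 0)
  b2 <- b; b2[1:3] <- NA
  expect_equal(sum(is.na(dichotomize_probes(b2, panel))), 3)
})

test_that("risk rule: n >= 5 concordant probes, unevaluable below 5 probes", {
  panel <- biomarker_panel()
  lowall <- panel$cutoff - 0.05
  mk <- function(n_low) {
    v <- panel$cutoff + 0.1
    v[seq_len(n_low)] <- lowall[seq_len(n_low)]
    panel_betas(v)
  }
  expect_equal(predict_risk_group(mk(5))$risk_group, "risk")
  expect_equal(predict_risk_group(mk(4))$risk_group, "non_risk")
  expect_equal(predict_risk_group(mk(7))$risk_group, "risk")
  few <- panel_betas(c(0.1, 0.1, 0.1, 0.1, NA, NA, NA))
  expect_equal(predict_risk_group(few)$risk_group, "unevaluable")
})

test_that("risk call is monotone and invariant to probe order and extras", {
  panel <- biomarker_panel()
  set.seed(13)
  for (i in 1:50) {
    v <- panel_betas(runif(7))
    base <- predict_risk_group(v)$risk_group
    j <- sample(7, 1)
    v2 <- v; v2[j] <- panel$cutoff[j] - 0.01   # force probe j concordant
    upg <- predict_risk_group(v2)$risk_group
    if (base == "risk") expect_equal(upg, "risk")
  }
  v <- panel_betas(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.9, 0.9))
  shuffled <- v[sample(7)]
  with_extra <- c(v, other1 = 0.99, other2 = 0.01)
  expect_equal(predict_risk_group(shuffled)$risk_group,
               predict_risk_group(v)$risk_group)
  expect_equal(predict_risk_group(with_extra)$risk_group,
               predict_risk_group(v)$risk_group)
})

test_that("panel validation reproduces the 2x2 arithmetic and degenerate case", {
  pred <- data.frame(
    sample_id = sprintf("s%03d", 1:271),
    n_evaluable = 7L, n_concordant = 0L,
    risk_group = c(rep("risk", 79), rep("non_risk", 192)),
    stringsAsFactors = FALSE)
  truth <- setNames(c(rep(TRUE, 20), rep(FALSE, 59),   # risk rows
                      TRUE, rep(FALSE, 191)),          # non-risk rows
                    pred$sample_id)
  v <- validate_panel(pred, truth)
  expect_equal(unname(v$table["risk", "positive"]), 20)
  expect_equal(v$odds_ratio, (20 * 191) / (59 * 1), tolerance = 1e-12)
  expect_equal(v$capture_rate, 20 / 21)
  expect_equal(v$risk_fraction, 79 / 271)
  expect_lt(v$p_value, 1e-10)

  pred$risk_group <- "non_risk"
  d <- validate_panel(pred, truth)
  expect_equal(d$p_value, 1)
})

test_that("random labels give null panel association on average", {
  set.seed(17)
  lors <- replicate(100, {
    pred <- data.frame(sample_id = sprintf("s%03d", 1:271),
                       n_evaluable = 7L, n_concordant = 0L,
                       risk_group = sample(c("risk", "non_risk"), 271,
                                           replace = TRUE, prob = c(.3, .7)))
    truth <- setNames(sample(c(TRUE, FALSE), 271, replace = TRUE,
                             prob = c(.1, .9)), pred$sample_id)
    log(validate_panel(pred, truth)$odds_ratio)
  })
  expect_lt(abs(mean(lors)), 0.2)
})

test_that("log-rank statistic matches the hand-worked small-sample case", {
  sheet <- data.frame(sample_id = paste0("s", 1:4),
                      patient_id = paste0("p", 1:4),
                      timepoint = "primary", fragment_index = 1L,
                      survival_time = c(1, 2, 3, 4),
                      survival_event = TRUE)
  groups <- setNames(c("g1", "g2", "g1", "g2"), paste0("p", 1:4))
  r <- km_logrank(sheet, groups)
  # O1 = 2, E1 = 1/2 + 1/3 + 1/2 = 4/3, V = 1/4 + 2/9 + 1/4 = 13/18
  expect_equal(r$logrank_chisq, (2 - 4 / 3)^2 / (13 / 18), tolerance = 1e-9)
  expect_true(all(diff(r$km$survival[r$km$group == "g1"]) <= 0))
})

test_that("identical group survival gives HR near 1 and non-significant log-rank", {
  set.seed(19)
  n <- 60
  sheet <- data.frame(sample_id = paste0("s", 1:n),
                      patient_id = paste0("p", 1:n),
                      timepoint = "primary", fragment_index = 1L,
                      survival_time = rexp(n, 0.1),
                      survival_event = TRUE)
  groups <- setNames(rep(c("a", "b"), n / 2), paste0("p", 1:n))
  r <- km_logrank(sheet, groups)
  expect_gt(r$logrank_p, 0.05)
  expect_lt(abs(log(r$hazard_ratio)), 0.6)
  expect_error(km_logrank(sheet, setNames(rep("a", n), paste0("p", 1:n))),
               "two")
})

test_that("end-to-end: planted panel risk patients are captured with survival signal", {
  lng <- long_cohort()
  primaries <- lng$beta[, paste0(lng$truth$patient_id, "_primary_1")]
  pr <- predict_risk_group(primaries)
  pat <- sub("_primary_1", "", pr$sample_id)
  truth <- setNames(lng$truth$risk_group[match(pat, lng$truth$patient_id)]
                    == "risk", pr$sample_id)
  sens <- mean(pr$risk_group[truth[pr$sample_id]] == "risk")
  expect_gte(sens, 0.9)
  grp <- setNames(ifelse(pr$risk_group == "risk", "risk", "non_risk"), pat)
  r <- km_logrank(lng$sheet, grp)
  expect_gt(r$hazard_ratio, 1)
})
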