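test_that("intermediate index rule matches the published windows", {
  expect_true(apply_intermediate_rule(c(gcimp_low = 0.30, gcimp_high = 0.60)))
  # lower bounds inclusive
  expect_true(apply_intermediate_rule(c(gcimp_low = 0.20, gcimp_high = 0.50)))
  expect_false(apply_intermediate_rule(c(gcimp_low = 0.05, gcimp_high = 0.90)))
  # upper bounds exclusive
  expect_false(apply_intermediate_rule(c(gcimp_low = 0.50, gcimp_high = 0.60)))
  expect_false(apply_intermediate_rule(c(gcimp_low = 0.30, gcimp_high = 0.75)))
  expect_error(apply_intermediate_rule(c(gcimp_low = 0.3)), "gcimp_high")
})

test_that("training validates labels and is deterministic under seed", {
  ref <- ref_cohort()
  labels <- truth_labels(ref)
  sub <- labels[labels != "pa_like"]
  expect_error(train_subtype_classifier(ref$beta[, names(sub)], sub,
                                        ref$signatures, n_trees = 10),
               "pa_like")
  m1 <- train_subtype_classifier(ref$beta, labels, ref$signatures,
                                 n_trees = 50, seed = 3)
  m2 <- train_subtype_classifier(ref$beta, labels, ref$signatures,
                                 n_trees = 50, seed = 3)
  q <- ref$beta[, 1:10]
  expect_identical(classify(m1, q), classify(m2, q))
  expect_true(all(m1$oob_accuracy > 0.9))
})

test_that("archetype-level samples classify to their subtype with saturated index", {
  m <- ref_model()
  # near-noiseless draws sit at the archetype mean
  pure <- generate_reference_cohort(cohort_config(
    n_patients_per_subtype = c(gcimp_high = 2, gcimp_low = 2, codel = 2,
                               classic_like = 2, mesenchymal_like = 2,
                               lgm6_gbm = 2, pa_like = 2),
    noise_concentration = 5000, seed = 77))
  res <- classify(m, pure$beta)
  expect_equal(res$subtype_argmax, unname(truth_labels(pure)[res$sample_id]))
  hi <- res[res$subtype_argmax == "gcimp_high", ]
  expect_true(all(hi$index_gcimp_high > 0.75))
  expect_false(any(hi$intermediate_flag))
})

test_that("per-tier indices are normalized vote fractions", {
  m <- ref_model()
  res <- classify(m, ref_cohort()$beta[, 1:12])
  mut_idx <- rowSums(res[, paste0("index_", c("codel", "gcimp_high",
                                              "gcimp_low"))])
  wt_idx <- rowSums(res[, paste0("index_", c("classic_like",
                                             "mesenchymal_like", "lgm6_gbm",
                                             "pa_like"))])
  expect_equal(mut_idx, rep(1, 12), tolerance = 1e-9)
  expect_equal(wt_idx, rep(1, 12), tolerance = 1e-9)
})

test_that("classification is invariant to sample order and background probes", {
  m <- ref_model()
  q <- ref_cohort()$beta[, 1:10]
  res <- classify(m, q)
  perm <- c(7, 2, 9, 1, 10, 3, 8, 4, 6, 5)
  res_p <- classify(m, q[, perm])
  expect_identical(res_p$sample_id, res$sample_id[perm])
  expect_identical(res_p$subtype, res$subtype[perm])

  set.seed(1)
  extra <- matrix(runif(1000 * ncol(q)), 1000,
                  dimnames = list(sprintf("junk%04d", 1:1000), colnames(q)))
  res_e <- classify(m, rbind(q, extra))
  expect_identical(res_e$subtype, res$subtype)
  expect_identical(res_e$index_gcimp_high, res$index_gcimp_high)
})

test_that("insufficient feature coverage is refused with a report", {
  m <- ref_model()
  q <- ref_cohort()$beta
  keep <- !rownames(q) %in% m$features$tier1[1:200]  # drop >10% of tier1
  expect_error(classify(m, q[keep, 1:3]), "coverage|features")
})

test_that("held-out accuracy is high at the default effect and chance at zero", {
  m <- ref_model()
  held <- generate_reference_cohort(cohort_config(n_patients_per_subtype = 5,
                                                  seed = 1234))
  acc <- classification_accuracy(classify(m, held$beta), truth_labels(held))
  expect_gt(acc, 0.95)

  # signature_effect 0: archetypes indistinguishable, accuracy near chance
  null_ref <- generate_reference_cohort(cohort_config(
    n_patients_per_subtype = 8, signature_effect = 0, seed = 8))
  m0 <- train_subtype_classifier(null_ref$beta, truth_labels(null_ref),
                                 null_ref$signatures, n_trees = 100, seed = 2)
  held0 <- generate_reference_cohort(cohort_config(
    n_patients_per_subtype = 8, signature_effect = 0, seed = 88))
  acc0 <- classification_accuracy(classify(m0, held0$beta), truth_labels(held0))
  expect_lt(acc0, 0.45)  # 7 classes, chance ~ 1/7
})

test_that("accuracy is non-decreasing in the signature effect", {
  accs <- vapply(c(0.05, 0.4), function(eff) {
    tr <- generate_reference_cohort(cohort_config(
      n_patients_per_subtype = 6, signature_effect = eff, seed = 21))
    te <- generate_reference_cohort(cohort_config(
      n_patients_per_subtype = 6, signature_effect = eff, seed = 22))
    m <- train_subtype_classifier(tr$beta, truth_labels(tr), tr$signatures,
                                  n_trees = 100, seed = 3)
    classification_accuracy(classify(m, te$beta), truth_labels(te))
  }, numeric(1))
  expect_true(diff(accs) >= 0)
})

test_that("cohort summary counts and percentages are consistent", {
  res <- data.frame(subtype = c(rep("gcimp_high", 3), "codel"))
  s <- cohort_summary(res)
  expect_equal(sum(s$n), 4)
  expect_equal(s$percent[s$subtype == "gcimp_high"], 75)
  expect_equal(cohort_summary(data.frame(subtype = "codel"))$percent, 100)
  expect_error(cohort_summary(character(0)), "empty")
})
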