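beta_from_rows <- function(rows, samples) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- samples
  m
}

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("rank-sum p-values: identity, complete separation, skip flags", {
  samples <- paste0("s", 1:8)
  A <- samples[1:4]; B <- samples[5:8]
  beta <- beta_from_rows(list(
    flat = rep(0.5, 8),
    sep = c(0.1, 0.15, 0.2, 0.25, 0.6, 0.7, 0.8, 0.9),
    holey = c(0.2, NA, NA, NA, 0.5, 0.6, 0.7, 0.8)), samples)
  tab <- wilcoxon_dmp(beta, A, B)
  expect_equal(tab$p_raw[tab$probe_id == "flat"], 1)
  expect_equal(tab$delta[tab$probe_id == "flat"], 0)
  # exact two-sided p for full separation at n = m = 4: 2 / C(8,4)
  expect_equal(tab$p_raw[tab$probe_id == "sep"], 2 / 70, tolerance = 1e-12)
  expect_true(tab$skipped[tab$probe_id == "holey"])
  expect_true(is.na(tab$p_raw[tab$probe_id == "holey"]))
  expect_true(all(tab$fdr >= tab$p_raw, na.rm = TRUE))
  expect_error(wilcoxon_dmp(beta, A, c(A[1], B)), "overlap")
  expect_error(wilcoxon_dmp(beta, A[1], B), ">= 2")
})

test_that("swapping the groups negates deltas, keeps p, exchanges directions", {
  set.seed(12)
  samples <- paste0("s", 1:12)
  beta <- matrix(runif(50 * 12), 50, 12,
                 dimnames = list(sprintf("cg%03d", 1:50), samples))
  beta[1:10, 1:6] <- beta[1:10, 1:6] * 0.3          # shifted block
  A <- samples[1:6]; B <- samples[7:12]
  ab <- wilcoxon_dmp(beta, A, B)
  ba <- wilcoxon_dmp(beta, B, A)
  expect_equal(ba$delta, -ab$delta)
  expect_equal(ba$p_raw, ab$p_raw)
  spec <- dmp_filter_spec("raw", 0.2, "absolute", abs_delta_min = 0.1)
  f_ab <- filter_dmps(ab, spec)
  f_ba <- filter_dmps(ba, spec)
  expect_setequal(f_ab$probe_id, f_ba$probe_id)
  m <- match(f_ab$probe_id, f_ba$probe_id)
  expect_true(all(f_ab$direction != f_ba$direction[m]))
})

test_that("filter specs enforce threshold arithmetic and handle empty tables", {
  spec <- dmp_preset("change_pair_712")
  tab <- data.frame(probe_id = c("a", "b", "c", "d"),
                    mean_a = 0, mean_b = 0,
                    delta = c(0.45, 0.55, -0.45, -0.35),
                    p_raw = 1e-6, fdr = 1e-5, skipped = FALSE)
  f <- filter_dmps(tab, spec)
  expect_identical(f$probe_id, c("b", "c"))  # 0.45 excluded by > 0.5 rule
  expect_identical(f$direction, c("hypo", "hyper"))

  empty <- filter_dmps(tab[0, ], spec)
  expect_equal(nrow(empty), 0)
  expect_equal(unname(attr(empty, "counts")), c(0L, 0L))

  expect_error(dmp_filter_spec("fdr", 0.05, "asymmetric"), "requires")
  expect_error(dmp_filter_spec("fdr", 0.05, "asymmetric",
                               hypo_delta_min = -0.5,
                               hyper_delta_max = -0.4))
})

test_that("planted differential probes are recovered with high sensitivity", {
  set.seed(31)
  n_planted <- 200; n_null <- 800
  samples <- paste0("s", 1:18)
  A <- samples[1:9]; B <- samples[10:18]
  draw <- function(mu, n) {
    x <- rbeta(n, mu * 50, (1 - mu) * 50)
    pmin(pmax(x, 1e-6), 1 - 1e-6)
  }
  planted <- t(vapply(seq_len(n_planted), function(i)
    c(draw(0.75, 9), draw(0.25, 9)), numeric(18)))
  null <- t(vapply(seq_len(n_null), function(i) draw(0.5, 18), numeric(18)))
  beta <- rbind(planted, null)
  dimnames(beta) <- list(c(sprintf("pl%04d", 1:n_planted),
                           sprintf("nl%04d", 1:n_null)), samples)
  tab <- wilcoxon_dmp(beta, A, B)
  f <- filter_dmps(tab, dmp_filter_spec("fdr", 0.05, "absolute",
                                        abs_delta_min = 0.2))
  sens <- mean(sprintf("pl%04d", 1:n_planted) %in% f$probe_id)
  expect_gte(sens, 0.9)
  expect_true(all(f$direction[grepl("^pl", f$probe_id)] == "hypo"))
})

test_that("null probes rarely pass the FDR + delta filter", {
  set.seed(7)
  n <- 5000
  samples <- paste0("s", 1:18)
  beta <- matrix(pmin(pmax(rbeta(n * 18, 25, 25), 1e-6), 1 - 1e-6), n, 18,
                 dimnames = list(sprintf("cg%05d", 1:n), samples))
  tab <- wilcoxon_dmp(beta, samples[1:9], samples[10:18])
  f <- filter_dmps(tab, dmp_filter_spec("fdr", 0.05, "absolute",
                                        abs_delta_min = 0.2))
  expect_lte(nrow(f) / n, 0.05)
})
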