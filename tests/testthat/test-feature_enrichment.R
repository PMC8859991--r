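mk_ann <- function(n, open_sea = 0, enhancer = rep(FALSE, n),
                   ap1 = rep(FALSE, n), sox = rep(FALSE, n)) {
  cgi <- rep("island", n)
  if (open_sea > 0) cgi[seq_len(open_sea)] <- "open_sea"
  data.frame(probe_id = sprintf("cg%05d", seq_len(n)),
             chromosome = "chr1", position = seq_len(n),
             cgi_relation = cgi, enhancer = enhancer,
             bivalent = FALSE, motif_AP1 = ap1, motif_SOX = sox,
             stringsAsFactors = FALSE)
}

test_that("genomic distribution reports half-up two-decimal percentages", {
  ann <- mk_ann(684, open_sea = 558)
  d <- genomic_distribution(ann$probe_id, ann)
  expect_equal(d$percent[d$category == "open_sea"], 81.58)
  expect_equal(d$n[d$category == "open_sea"], 558L)

  one <- mk_ann(10, open_sea = 10)
  d1 <- genomic_distribution(one$probe_id, one)
  expect_equal(d1$percent, 100)
  # unannotated probes are excluded and reported
  d2 <- genomic_distribution(c(ann$probe_id[1:10], "zz1"), ann)
  expect_equal(sum(d2$n), 10)
  expect_equal(attr(d2, "missing"), "zz1")
  expect_error(genomic_distribution(character(0), ann), "empty")
})

test_that("odds ratio and Woolf CI match the closed forms", {
  r <- odds_ratio_ci(10, 10, 10, 10)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$call, "ns")

  r2 <- odds_ratio_ci(20, 80, 100, 800)
  expect_equal(r2$odds_ratio, 2)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 800)
  expect_equal(r2$ci_low, exp(log(2) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r2$ci_high, exp(log(2) + qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(c(r2$ci_low, r2$ci_high), c(1.175, 3.406), tolerance = 0.001)
  expect_equal(r2$call, "enriched")

  # Haldane-Anscombe correction on a zero cell
  r3 <- odds_ratio_ci(0, 10, 10, 10)
  expect_equal(r3$odds_ratio, (0.5 * 10.5) / (10.5 * 10.5), tolerance = 1e-12)
  expect_true(is.finite(r3$ci_low) && is.finite(r3$ci_high))
  expect_error(odds_ratio_ci(0, 0, 5, 5), "empty")
})

test_that("OR of a binary feature is the reciprocal of its complement", {
  set.seed(3)
  for (i in 1:20) {
    cells <- sample(1:50, 4, replace = TRUE)
    r <- odds_ratio_ci(cells[1], cells[2], cells[3], cells[4])
    rc <- odds_ratio_ci(cells[2], cells[1], cells[4], cells[3])
    expect_equal(r$odds_ratio * rc$odds_ratio, 1, tolerance = 1e-12)
    expect_equal(r$p, rc$p, tolerance = 1e-12)
  }
})

test_that("Fisher p agrees with the exhaustive hypergeometric tail sum", {
  # two-sided by the probability method, margins <= 30
  brute_fisher <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(9)
  for (i in 1:50) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    r <- odds_ratio_ci(a, b, c_, d)
    expect_equal(r$p, brute_fisher(a, b, c_, d), tolerance = 1e-7)
  }
})

test_that("set enrichment uses the array-wide background and BH across features", {
  ann <- mk_ann(1000, open_sea = 300,
                enhancer = c(rep(TRUE, 150), rep(FALSE, 850)))
  sel <- ann$probe_id[1:100]  # all open_sea, all enhancer for first 100
  r <- odds_ratio_enrichment(sel, ann, "cgi_relation=open_sea")
  expect_equal(r$a + r$b, 100)
  expect_equal(r$c + r$d, 900)
  expect_equal(r$call, "enriched")
  tab <- enrichment_table(sel, ann, c("cgi_relation=open_sea", "enhancer",
                                      "bivalent"))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$fdr >= tab$p))
})

test_that("motif overlap fractions and intersections are exact", {
  ann <- mk_ann(684, ap1 = c(rep(TRUE, 80), rep(FALSE, 604)),
                sox = c(rep(TRUE, 35), rep(FALSE, 649)))
  r <- motif_overlap_fraction(ann$probe_id, ann, c("AP1", "SOX"))
  expect_equal(r$n_overlap, 80)
  expect_equal(r$fraction, 11.70)
  expect_equal(r$n_both, 35)
  expect_equal(r$fraction_both, 5.12)
  none <- motif_overlap_fraction(ann$probe_id[100:110], ann, "AP1")
  expect_equal(none$fraction, 0)
  expect_error(motif_overlap_fraction(ann$probe_id, ann, "NOPE"), "motif")
})

test_that("planted enrichment of the transition probes is called across seeds", {
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    lng <- generate_longitudinal_cohort(cohort_config(
      n_patients_per_subtype = c(gcimp_high = 4), seed = seed))
    et <- enrichment_table(lng$planted$dmp_hypo, lng$annotation,
                           c("cgi_relation=open_sea", "enhancer",
                             "motif_AP1", "motif_SOX"))
    hits <- hits + sum(et$call == "enriched")
    total <- total + nrow(et)
  }
  expect_gte(hits / total, 0.9)
})
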