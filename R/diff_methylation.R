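# Supervised per-probe differential methylation between two sample groups:
# Wilcoxon rank-sum tests, Benjamini-Hochberg adjustment, and the named
# delta-beta filter presets used in the longitudinal glioma analyses.
#
# Convention: delta = mean(groupA) - mean(groupB), with groupA the
# reference (earlier/primary) group and groupB the case (recurrent) group
# in the named presets, so a large positive delta marks a probe
# demethylated in the case group ("hypo" direction) and a large negative
# delta a probe that gained methylation in the case group ("hyper").

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0,1\] (NA passed through)
#' @return adjusted values, input order preserved
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe Wilcoxon rank-sum differential methylation
#'
#' Two-sided rank-sum p per probe: exact when the combined group size is
#' <= 20 and the probe has no ties, otherwise the normal approximation with
#' tie and continuity correction. Group means ignore missing values; probes
#' with fewer than two non-missing values in either group are flagged
#' `skipped` with NA statistics.
#'
#' @param beta beta matrix
#' @param groupA,groupB disjoint sample-ID vectors (each >= 2 samples);
#'   `groupA` is the reference group of the delta convention above
#' @return data.frame (DmpTable): probe_id, mean_a, mean_b, delta, p_raw,
#'   fdr, skipped
#' @export
wilcoxon_dmp <- function(beta, groupA, groupB) {
  validate_beta_matrix(beta)
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(head(intersect(groupA, groupB), 3),
                                   collapse = ", "))
  miss <- setdiff(c(groupA, groupB), colnames(beta))
  if (length(miss)) stop("sample(s) absent from beta matrix: ",
                         paste(head(miss, 5), collapse = ", "))
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need >= 2 samples")
  A <- beta[, groupA, drop = FALSE]
  B <- beta[, groupB, drop = FALSE]
  n_probe <- nrow(beta)
  mean_a <- rowMeans(A, na.rm = TRUE)
  mean_b <- rowMeans(B, na.rm = TRUE)
  p_raw <- rep(NA_real_, n_probe)
  skipped <- logical(n_probe)
  for (i in seq_len(n_probe)) {
    x <- A[i, ][!is.na(A[i, ])]
    y <- B[i, ][!is.na(B[i, ])]
    if (length(x) < 2 || length(y) < 2) {
      skipped[i] <- TRUE
      next
    }
    if (max(c(x, y)) == min(c(x, y))) {
      p_raw[i] <- 1  # fully tied probe: no evidence either way
      next
    }
    exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
    p_raw[i] <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  }
  data.frame(probe_id = rownames(beta), mean_a = mean_a, mean_b = mean_b,
             delta = mean_a - mean_b, p_raw = p_raw, fdr = bh_adjust(p_raw),
             skipped = skipped, stringsAsFactors = FALSE, row.names = NULL)
}

#' Delta-beta filter specification
#'
#' `absolute` mode keeps probes meeting the p criterion with
#' `|delta| > abs_delta_min`; `asymmetric` mode keeps probes with
#' `delta > hypo_delta_min` (direction `hypo`, demethylated in the case
#' group) or `delta < hyper_delta_max` (direction `hyper`).
#'
#' @param p_mode `"fdr"` or `"raw"`
#' @param p_max p/FDR threshold
#' @param delta_mode `"absolute"` or `"asymmetric"`
#' @param abs_delta_min absolute-delta threshold (absolute mode)
#' @param hypo_delta_min positive threshold on delta (asymmetric mode)
#' @param hyper_delta_max negative threshold on delta (asymmetric mode)
#' @return list of class `dmp_filter_spec`
#' @export
dmp_filter_spec <- function(p_mode = c("fdr", "raw"), p_max = 0.05,
                            delta_mode = c("absolute", "asymmetric"),
                            abs_delta_min = 0.2,
                            hypo_delta_min = NULL, hyper_delta_max = NULL) {
  p_mode <- match.arg(p_mode)
  delta_mode <- match.arg(delta_mode)
  stopifnot(p_max > 0, p_max <= 1)
  if (delta_mode == "asymmetric") {
    if (is.null(hypo_delta_min) || is.null(hyper_delta_max))
      stop("asymmetric mode requires hypo_delta_min and hyper_delta_max")
    stopifnot(hypo_delta_min > 0, hyper_delta_max < 0)
  } else {
    stopifnot(abs_delta_min > 0, abs_delta_min < 1)
  }
  structure(list(p_mode = p_mode, p_max = p_max, delta_mode = delta_mode,
                 abs_delta_min = abs_delta_min,
                 hypo_delta_min = hypo_delta_min,
                 hyper_delta_max = hyper_delta_max),
            class = "dmp_filter_spec")
}

#' Named filter presets of the longitudinal glioma analyses
#'
#' * `gcimp_low_primary_vs_recurrent` — FDR < 0.05, |delta| > 0.2
#'   (the 84-probe de-novo vs acquired G-CIMP-low comparison)
#' * `change_pair_712` — FDR < 0.05, delta > 0.5 (hypo) / < -0.4 (hyper)
#'   (the 684 + 28 probe G-CIMP-high primary vs G-CIMP-low recurrence set)
#' * `grade4_recurrent_350` — raw p < 0.01, delta > 0.5 / < -0.4
#' * `biomarker_discovery_7` — raw p < 0.05, |delta| > 0.2 (7-CpG panel
#'   discovery)
#'
#' In every preset groupA is the reference (primary / retaining) group and
#' groupB the case (recurrent / progressing) group.
#'
#' @param name preset name
#' @return a [dmp_filter_spec()]
#' @export
dmp_preset <- function(name = c("gcimp_low_primary_vs_recurrent",
                                "change_pair_712", "grade4_recurrent_350",
                                "biomarker_discovery_7")) {
  name <- match.arg(name)
  switch(name,
    gcimp_low_primary_vs_recurrent =
      dmp_filter_spec("fdr", 0.05, "absolute", abs_delta_min = 0.2),
    change_pair_712 =
      dmp_filter_spec("fdr", 0.05, "asymmetric",
                      hypo_delta_min = 0.5, hyper_delta_max = -0.4),
    grade4_recurrent_350 =
      dmp_filter_spec("raw", 0.01, "asymmetric",
                      hypo_delta_min = 0.5, hyper_delta_max = -0.4),
    biomarker_discovery_7 =
      dmp_filter_spec("raw", 0.05, "absolute", abs_delta_min = 0.2))
}

#' Filter a DmpTable and assign direction labels
#'
#' @param table output of [wilcoxon_dmp()]
#' @param spec a [dmp_filter_spec()] or [dmp_preset()] name
#' @return the filtered table with a `direction` column (`hypo` =
#'   demethylated in the case group, `hyper` = methylation gained), plus
#'   attribute `counts` with per-direction totals
#' @export
filter_dmps <- function(table, spec) {
  if (is.character(spec)) spec <- dmp_preset(spec)
  stopifnot(inherits(spec, "dmp_filter_spec"))
  req <- c("probe_id", "delta", "p_raw", "fdr")
  if (!all(req %in% names(table)))
    stop("table lacks DmpTable columns: ",
         paste(setdiff(req, names(table)), collapse = ", "))
  if (!nrow(table)) {
    out <- table
    out$direction <- character(0)
    attr(out, "counts") <- c(hypo = 0L, hyper = 0L)
    return(out)
  }
  pv <- if (spec$p_mode == "fdr") table$fdr else table$p_raw
  p_ok <- !is.na(pv) & pv < spec$p_max
  if (spec$delta_mode == "absolute") {
    keep <- p_ok & abs(table$delta) > spec$abs_delta_min
    direction <- ifelse(table$delta > 0, "hypo", "hyper")
  } else {
    hypo <- p_ok & table$delta > spec$hypo_delta_min
    hyper <- p_ok & table$delta < spec$hyper_delta_max
    keep <- hypo | hyper
    direction <- ifelse(hypo, "hypo", "hyper")
  }
  out <- table[keep, , drop = FALSE]
  out$direction <- direction[keep]
  rownames(out) <- NULL
  attr(out, "counts") <- c(hypo = sum(out$direction == "hypo"),
                           hyper = sum(out$direction == "hyper"))
  out
}
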