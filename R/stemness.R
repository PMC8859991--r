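# DNA-methylation stemness index (mDNAsi): a weighted linear score over the
# stemness signature probes, min-max scaled to [0,1] across the scored
# cohort, averaged across fragments per patient-surgery.

#' Compute the mDNAsi stemness index
#'
#' Raw score per sample is the inner product of the signature weights with
#' the sample's beta values over the retained signature probes (missing
#' probes are dropped and the score renormalized by the retained weight
#' count so samples remain comparable); scaled scores are cohort-relative
#' min-max. When the sample sheet is supplied, fragment scores are averaged
#' per patient-surgery.
#'
#' @param beta beta matrix
#' @param weights stemness signature list with a `weights` vector (e.g.
#'   [generate_stemness_weights()])
#' @param sheet optional sample sheet for per-surgery averaging
#' @return list: `scores` (data.frame sample_id, raw, mdnasi),
#'   `surgery_means` (patient_id, timepoint, mdnasi_mean; NULL without a
#'   sheet)
#' @export
compute_mdnasi <- function(beta, weights, sheet = NULL) {
  validate_beta_matrix(beta)
  w <- weights$weights
  if (is.null(w)) stop("signature carries no weights")
  present <- intersect(names(w), rownames(beta))
  if (length(present) / length(w) < 0.9)
    stop(sprintf("only %d of %d weighted probes present (>= 90%% required)",
                 length(present), length(w)))
  sub <- beta[present, , drop = FALSE]
  wp <- w[present]
  raw <- vapply(seq_len(ncol(sub)), function(j) {
    ok <- !is.na(sub[, j])
    if (!any(ok)) return(NA_real_)
    # renormalize by retained weight count so missingness does not shrink
    sum(wp[ok] * sub[ok, j]) * length(wp) / sum(ok)
  }, numeric(1))
  rng <- range(raw, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("all raw stemness scores identical; scaled scores set to 0")
    scaled <- rep(0, length(raw))
  } else {
    scaled <- (raw - rng[1]) / diff(rng)
  }
  scores <- data.frame(sample_id = colnames(beta), raw = raw,
                       mdnasi = scaled, stringsAsFactors = FALSE)
  surgery_means <- NULL
  if (!is.null(sheet)) {
    m <- merge(scores, sheet[, c("sample_id", "patient_id", "timepoint")],
               by = "sample_id")
    agg <- stats::aggregate(mdnasi ~ patient_id + timepoint, data = m, FUN = mean)
    names(agg)[names(agg) == "mdnasi"] <- "mdnasi_mean"
    surgery_means <- agg[order(agg$patient_id, agg$timepoint), ]
    rownames(surgery_means) <- NULL
  }
  list(scores = scores, surgery_means = surgery_means)
}

#' Compare stemness between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the scaled mDNAsi scores.
#'
#' @param scores `scores` data.frame from [compute_mdnasi()]
#' @param groups named character vector (names = sample IDs) with exactly
#'   two distinct group labels
#' @return list: per-group `n` and `median`, `p_value`
#' @export
compare_stemness_groups <- function(scores, groups) {
  g <- groups[scores$sample_id]
  keep <- !is.na(g)
  g <- factor(g[keep])
  x <- scores$mdnasi[keep]
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) == 0)) stop("empty group")
  med <- tapply(x, g, median)
  p <- suppressWarnings(
    stats::wilcox.test(x ~ g, exact = length(x) <= 20)$p.value)
  list(groups = levels(g), n = as.integer(table(g)),
       median = as.numeric(med), p_value = p)
}
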