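# Genomic-feature statistics for probe sets: category distributions,
# odds-ratio enrichment/depletion against the array background (Woolf
# log-OR confidence intervals, Fisher exact p), and motif-hit overlap
# fractions.

#' Per-category distribution of a probe set over an annotation column
#'
#' @param probes probe-ID set
#' @param annotation probe annotation data.frame
#' @param field annotation column (e.g. `"cgi_relation"`, `"chromosome"`)
#' @return data.frame: category, n, percent (two decimals, half-up),
#'   computed over annotated probes; attribute `missing` lists
#'   unannotated probe IDs
#' @export
genomic_distribution <- function(probes, annotation, field = "cgi_relation") {
  probes <- unique(as.character(probes))
  if (!length(probes)) stop("empty probe set")
  if (!field %in% names(annotation)) stop("unknown annotation field: ", field)
  found <- probes %in% annotation$probe_id
  ann <- annotation[match(probes[found], annotation$probe_id), ]
  if (!nrow(ann)) stop("no probes annotated")
  tab <- table(ann[[field]])
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- percent_of(out$n, sum(out$n))
  out <- out[order(-out$n), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- probes[!found]
  out
}

#' Odds-ratio enrichment of a binary feature from 2x2 counts
#'
#' OR = (a*d)/(b*c) with the Haldane-Anscombe 0.5 continuity correction
#' applied to all cells only when any cell is zero; 95% CI by the Woolf
#' (log-OR normal) method. Two-sided Fisher exact p from the uncorrected
#' table. Call: `enriched` when ci_low > 1, `depleted` when ci_high < 1,
#' otherwise `ns`.
#'
#' @param a,b selected probes with / without the feature
#' @param c_,d_ background probes with / without the feature
#' @param feature feature name carried into the output
#' @param conf_method `"woolf"` (default) or `"exact"` (conditional CI from
#'   [stats::fisher.test()])
#' @return one-row data.frame (EnrichmentRow): feature, a, b, c, d,
#'   odds_ratio, ci_low, ci_high, p, call
#' @export
odds_ratio_ci <- function(a, b, c_, d_, feature = "feature",
                          conf_method = c("woolf", "exact")) {
  conf_method <- match.arg(conf_method)
  stopifnot(a >= 0, b >= 0, c_ >= 0, d_ >= 0)
  if ((a + b) == 0 || (c_ + d_) == 0)
    stop("empty selected or background set")
  p <- stats::fisher.test(matrix(c(a, b, c_, d_), 2, byrow = TRUE))$p.value
  cells <- c(a, b, c_, d_)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  if (conf_method == "woolf") {
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    ft <- stats::fisher.test(matrix(c(a, b, c_, d_), 2, byrow = TRUE))
    ci <- as.numeric(ft$conf.int)
  }
  call <- if (ci[1] > 1) "enriched" else if (ci[2] < 1) "depleted" else "ns"
  data.frame(feature = feature, a = a, b = b, c = c_, d = d_,
             odds_ratio = or, ci_low = ci[1], ci_high = ci[2], p = p,
             call = call, stringsAsFactors = FALSE)
}

feature_flags <- function(annotation, feature) {
  if (feature %in% names(annotation) && is.logical(annotation[[feature]]))
    return(setNames(annotation[[feature]], annotation$probe_id))
  # categorical features addressed as column=value, e.g. cgi_relation=open_sea
  if (grepl("=", feature, fixed = TRUE)) {
    parts <- strsplit(feature, "=", fixed = TRUE)[[1]]
    col <- parts[1]; val <- parts[2]
    if (!col %in% names(annotation)) stop("unknown feature: ", feature)
    return(setNames(annotation[[col]] == val, annotation$probe_id))
  }
  stop("unknown feature: ", feature)
}

#' Odds-ratio enrichment of a probe set for an annotated feature
#'
#' Background defaults to all annotated probes minus the selected set (the
#' array-wide universe); a custom universe may be supplied.
#'
#' @param selected probe-ID set
#' @param annotation probe annotation
#' @param feature logical annotation column, or `"column=value"` for a
#'   categorical one (e.g. `"cgi_relation=open_sea"`)
#' @param universe optional probe-ID universe (default: all annotated)
#' @param conf_method see [odds_ratio_ci()]
#' @return one-row EnrichmentRow data.frame
#' @export
odds_ratio_enrichment <- function(selected, annotation, feature,
                                  universe = NULL,
                                  conf_method = c("woolf", "exact")) {
  selected <- unique(as.character(selected))
  if (!length(selected)) stop("empty selected set")
  flags <- feature_flags(annotation, feature)
  if (is.null(universe)) universe <- annotation$probe_id
  background <- setdiff(universe, selected)
  if (!length(background)) stop("empty background set")
  sel_f <- flags[intersect(selected, names(flags))]
  bg_f <- flags[intersect(background, names(flags))]
  odds_ratio_ci(sum(sel_f), sum(!sel_f), sum(bg_f), sum(!bg_f),
                feature = feature, conf_method = match.arg(conf_method))
}

#' Enrichment of a probe set across several features
#'
#' One EnrichmentRow per feature with BH-adjusted p alongside the raw
#' Fisher p.
#'
#' @inheritParams odds_ratio_enrichment
#' @param features character vector of features
#' @return data.frame of EnrichmentRows plus an `fdr` column
#' @export
enrichment_table <- function(selected, annotation, features,
                             universe = NULL) {
  rows <- do.call(rbind, lapply(features, function(f)
    odds_ratio_enrichment(selected, annotation, f, universe)))
  rows$fdr <- bh_adjust(rows$p)
  rows
}

#' Motif-hit overlap of a probe set
#'
#' Overlap count and fraction of the set carrying the motif flag, with the
#' odds-ratio enrichment row against the background universe. With two
#' motifs, also reports the intersection carrying both.
#'
#' @param dmr_set probe-ID set
#' @param annotation probe annotation with `motif_<name>` columns
#' @param motif motif name (e.g. `"AP1"`), or two names for the
#'   intersection report
#' @param universe optional background universe
#' @return list: `n_overlap`, `fraction` (percent, two decimals),
#'   `enrichment` (EnrichmentRow); with two motifs additionally
#'   `n_both`/`fraction_both`
#' @export
motif_overlap_fraction <- function(dmr_set, annotation, motif,
                                   universe = NULL) {
  dmr_set <- unique(as.character(dmr_set))
  cols <- paste0("motif_", motif)
  miss <- setdiff(cols, names(annotation))
  if (length(miss)) stop("unknown motif flag(s): ",
                         paste(sub("motif_", "", miss), collapse = ", "))
  flags <- setNames(annotation[[cols[1]]], annotation$probe_id)
  hit <- flags[intersect(dmr_set, names(flags))]
  background <- setdiff(universe %||% annotation$probe_id, dmr_set)
  out <- list(
    n_overlap = sum(hit),
    fraction = percent_of(sum(hit), length(dmr_set)),
    # enrichment is undefined when the set exhausts the annotation universe
    enrichment = if (length(background))
      odds_ratio_enrichment(dmr_set, annotation, cols[1], universe))
  if (length(cols) == 2) {
    flags2 <- setNames(annotation[[cols[2]]], annotation$probe_id)
    both <- hit & flags2[names(hit)]
    out$n_both <- sum(both)
    out$fraction_both <- percent_of(sum(both), length(dmr_set))
  }
  out
}
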