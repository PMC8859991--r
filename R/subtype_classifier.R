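# Two-tier reference-signature random-forest subtype classifier.
# Tier 1 separates the IDH-mutant from the IDH-wild-type macro group on the
# 1,300 macro-group signature probes; tier 2 resolves the within-macro
# subtype (codel / gcimp_high / gcimp_low on the 1,308 + 163 IDH-mutant
# signatures, classic_like / mesenchymal_like / lgm6_gbm / pa_like on the
# 914 IDH-wild-type signature). Per-class probability indices are the
# fraction of trees voting for the class; the G-CIMP-intermediate rule is
# applied afterwards on the gcimp_low/gcimp_high indices.

MACRO_LEVELS <- c("idh_mutant", "idh_wildtype")

macro_of_subtype <- function(subtype) {
  ifelse(subtype %in% IDH_MUT_SUBTYPES, "idh_mutant", "idh_wildtype")
}

#' G-CIMP-intermediate index rule
#'
#' Index windows defining the G-CIMP-intermediate call: gcimp_low index in
#' \[0.2, 0.5) and gcimp_high index in \[0.5, 0.75), lower bounds inclusive.
#'
#' @param low_min,low_max window on the gcimp_low index
#' @param high_min,high_max window on the gcimp_high index
#' @return list of class `intermediate_rule`
#' @export
intermediate_rule <- function(low_min = 0.2, low_max = 0.5,
                              high_min = 0.5, high_max = 0.75) {
  stopifnot(low_min < low_max, high_min < high_max)
  structure(list(low_min = low_min, low_max = low_max,
                 high_min = high_min, high_max = high_max),
            class = "intermediate_rule")
}

#' Apply the G-CIMP-intermediate rule to a set of class indices
#'
#' @param indices named numeric vector containing `gcimp_low` and
#'   `gcimp_high` entries
#' @param rule an [intermediate_rule()]
#' @return TRUE iff both indices fall inside the intermediate windows
#' @export
apply_intermediate_rule <- function(indices, rule = intermediate_rule()) {
  if (!all(c("gcimp_low", "gcimp_high") %in% names(indices)))
    stop("indices must contain gcimp_low and gcimp_high entries")
  lo <- indices[["gcimp_low"]]
  hi <- indices[["gcimp_high"]]
  lo >= rule$low_min && lo < rule$low_max &&
    hi >= rule$high_min && hi < rule$high_max
}

fit_forest <- function(x, y, n_trees, seed) {
  set.seed(seed)
  y <- factor(y)
  randomForest::randomForest(x = x, y = y, ntree = n_trees)
}

# training-sample feature matrix for one tier: samples x probes, ordered by
# the recorded feature list
tier_features <- function(beta, feature_probes) {
  present <- feature_probes[feature_probes %in% rownames(beta)]
  t(beta[present, , drop = FALSE])
}

#' Train the two-tier subtype classifier
#'
#' @param beta reference beta matrix (probes x samples)
#' @param labels named character vector (or vector ordered as `colnames(beta)`)
#'   of true subtype labels over the 7 subtypes
#' @param signatures list of signature sets containing `macro_1300`,
#'   `idh_mut_1308`, `idh_mut_subtype_163` and `idh_wt_914`
#' @param n_trees trees per forest (default 500)
#' @param seed integer seed; forests are refit deterministically from it
#' @param flat also fit a flat 7-class forest over all signature probes,
#'   available for comparison via `classify(..., tier = "flat")`
#' @return a `subtype_classifier` model with per-tier out-of-bag accuracy,
#'   feature lists, training feature means (for imputation) and class orders
#' @export
train_subtype_classifier <- function(beta, labels, signatures,
                                     n_trees = 500, seed = 42,
                                     flat = FALSE) {
  validate_beta_matrix(beta)
  if (!is.null(names(labels))) labels <- labels[colnames(beta)]
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(beta))
  missing_classes <- setdiff(SUBTYPE_LEVELS, labels)
  if (length(missing_classes))
    stop("training labels missing class(es): ",
         paste(missing_classes, collapse = ", "))
  if (any(table(labels) < 2))
    stop("every class needs >= 2 training samples")

  feats <- list(
    tier1 = signatures$macro_1300$probe_ids,
    tier2_mut = unique(c(signatures$idh_mut_1308$probe_ids,
                         signatures$idh_mut_subtype_163$probe_ids)),
    tier2_wt = signatures$idh_wt_914$probe_ids)
  dropped <- lapply(feats, function(p) setdiff(p, rownames(beta)))
  if (any(lengths(dropped) > 0))
    warning("signature probes absent from training matrix dropped: ",
            sum(lengths(dropped)))

  x1 <- tier_features(beta, feats$tier1)
  macro <- macro_of_subtype(labels)
  t1 <- fit_forest(x1, factor(macro, levels = MACRO_LEVELS), n_trees,
                   derive_seed(seed, "tier1"))

  mut_idx <- which(macro == "idh_mutant")
  x2m <- tier_features(beta[, mut_idx, drop = FALSE], feats$tier2_mut)
  t2m <- fit_forest(x2m, factor(labels[mut_idx], levels = IDH_MUT_SUBTYPES),
                    n_trees, derive_seed(seed, "tier2_mut"))

  wt_idx <- which(macro == "idh_wildtype")
  x2w <- tier_features(beta[, wt_idx, drop = FALSE], feats$tier2_wt)
  t2w <- fit_forest(x2w, factor(labels[wt_idx], levels = IDH_WT_SUBTYPES),
                    n_trees, derive_seed(seed, "tier2_wt"))

  model <- list(
    tier1 = t1, tier2_mut = t2m, tier2_wt = t2w,
    features = lapply(list(tier1 = x1, tier2_mut = x2m, tier2_wt = x2w),
                      colnames),
    train_means = lapply(list(tier1 = x1, tier2_mut = x2m, tier2_wt = x2w),
                         colMeans),
    oob_accuracy = c(
      tier1 = 1 - t1$err.rate[n_trees, "OOB"],
      tier2_mut = 1 - t2m$err.rate[n_trees, "OOB"],
      tier2_wt = 1 - t2w$err.rate[n_trees, "OOB"]),
    class_order = list(macro = MACRO_LEVELS, mut = IDH_MUT_SUBTYPES,
                       wt = IDH_WT_SUBTYPES),
    n_trees = n_trees, seed = seed)
  if (flat) {
    all_feats <- unique(unlist(feats))
    xf <- tier_features(beta, all_feats)
    model$flat <- fit_forest(xf, factor(labels, levels = SUBTYPE_LEVELS),
                             n_trees, derive_seed(seed, "flat"))
    model$features$flat <- colnames(xf)
    model$train_means$flat <- colMeans(xf)
  }
  class(model) <- "subtype_classifier"
  model
}

# query feature matrix for one tier, imputing missing probes (<= 10%) with
# training means
query_features <- function(beta, model, tier) {
  feats <- model$features[[tier]]
  present <- intersect(feats, rownames(beta))
  coverage <- length(present) / length(feats)
  if (coverage < 0.9)
    stop(sprintf("query covers %.1f%% of %s features (>= 90%% required)",
                 100 * coverage, tier))
  x <- matrix(NA_real_, ncol(beta), length(feats),
              dimnames = list(colnames(beta), feats))
  x[, present] <- t(beta[present, , drop = FALSE])
  missing <- setdiff(feats, present)
  if (length(missing))
    x[, missing] <- rep(model$train_means[[tier]][missing],
                        each = nrow(x))
  # residual per-cell missing values also fall back to training means
  if (anyNA(x)) {
    for (jcol in which(colSums(is.na(x)) > 0))
      x[is.na(x[, jcol]), jcol] <- model$train_means[[tier]][jcol]
  }
  x
}

vote_fractions <- function(forest, x) {
  v <- stats::predict(forest, newdata = x, type = "vote", norm.votes = TRUE)
  v[is.na(v)] <- 0
  v
}

argmax_label <- function(votes, class_order) {
  # fixed class order breaks ties deterministically
  v <- votes[, class_order, drop = FALSE]
  class_order[apply(v, 1, which.max)]
}

#' Classify query samples into the seven methylation subtypes
#'
#' Runs tier 1 for the macro-group call, then the matching tier-2 forest
#' for the subtype; both tier-2 index sets are reported for every sample.
#' IDH-mutant samples whose argmax subtype is gcimp_high or gcimp_low are
#' relabeled `gcimp_intermediate` when their indices fall in the
#' intermediate windows (the argmax label is kept in `subtype_argmax`).
#'
#' @param model a trained [train_subtype_classifier()] model
#' @param beta query beta matrix
#' @param rule an [intermediate_rule()]
#' @param tier `"two_tier"` (default) or `"flat"` (requires a model trained
#'   with `flat = TRUE`)
#' @return data.frame: sample_id, macro_group, subtype, subtype_argmax,
#'   intermediate_flag, one index column per class (`index_<class>`) plus
#'   `index_idh_mutant`
#' @export
classify <- function(model, beta, rule = intermediate_rule(),
                     tier = c("two_tier", "flat")) {
  stopifnot(inherits(model, "subtype_classifier"))
  tier <- match.arg(tier)
  validate_beta_matrix(beta)

  if (tier == "flat") {
    if (is.null(model$flat)) stop("model was trained without flat = TRUE")
    vf <- vote_fractions(model$flat, query_features(beta, model, "flat"))
    sub <- argmax_label(vf, SUBTYPE_LEVELS)
    res <- data.frame(sample_id = colnames(beta),
                      macro_group = macro_of_subtype(sub),
                      subtype = sub, subtype_argmax = sub,
                      intermediate_flag = FALSE,
                      stringsAsFactors = FALSE)
    for (cl in SUBTYPE_LEVELS) res[[paste0("index_", cl)]] <- vf[, cl]
    return(res)
  }

  v1 <- vote_fractions(model$tier1, query_features(beta, model, "tier1"))
  macro <- argmax_label(v1, MACRO_LEVELS)
  v2m <- vote_fractions(model$tier2_mut,
                        query_features(beta, model, "tier2_mut"))
  v2w <- vote_fractions(model$tier2_wt,
                        query_features(beta, model, "tier2_wt"))

  sub_mut <- argmax_label(v2m, IDH_MUT_SUBTYPES)
  sub_wt <- argmax_label(v2w, IDH_WT_SUBTYPES)
  subtype_argmax <- ifelse(macro == "idh_mutant", sub_mut, sub_wt)

  n <- ncol(beta)
  inter <- logical(n)
  for (i in seq_len(n)) {
    # the rule applies only within the IDH-mutant non-codel G-CIMP calls
    if (macro[i] == "idh_mutant" &&
        subtype_argmax[i] %in% c("gcimp_high", "gcimp_low")) {
      inter[i] <- apply_intermediate_rule(
        c(gcimp_low = v2m[i, "gcimp_low"], gcimp_high = v2m[i, "gcimp_high"]),
        rule)
    }
  }
  res <- data.frame(sample_id = colnames(beta), macro_group = macro,
                    subtype = ifelse(inter, "gcimp_intermediate",
                                     subtype_argmax),
                    subtype_argmax = subtype_argmax,
                    intermediate_flag = inter, stringsAsFactors = FALSE)
  res$index_idh_mutant <- v1[, "idh_mutant"]
  for (cl in IDH_MUT_SUBTYPES) res[[paste0("index_", cl)]] <- v2m[, cl]
  for (cl in IDH_WT_SUBTYPES) res[[paste0("index_", cl)]] <- v2w[, cl]
  rownames(res) <- NULL
  res
}

#' Held-out accuracy of classification results against true labels
#'
#' Compares the argmax subtype (the intermediate relabel is an annotation
#' of borderline index profiles, not one of the seven training classes).
#'
#' @param results output of [classify()]
#' @param truth_labels named character vector, names = sample IDs
#' @return fraction of correctly labeled samples
#' @export
classification_accuracy <- function(results, truth_labels) {
  mean(results$subtype_argmax == truth_labels[results$sample_id])
}

#' Stratified k-fold cross-validated accuracy of the two-tier classifier
#'
#' @param beta reference beta matrix
#' @param labels true subtype labels (named by sample or ordered as columns)
#' @param signatures signature set collection
#' @param n_folds folds (default 10)
#' @param n_trees trees per forest
#' @param seed integer seed (fold assignment and forests)
#' @return list with per-fold accuracies and their mean
#' @export
cv_subtype_classifier <- function(beta, labels, signatures, n_folds = 10,
                                  n_trees = 500, seed = 42) {
  if (!is.null(names(labels))) labels <- labels[colnames(beta)]
  labels <- as.character(labels)
  set.seed(derive_seed(seed, "cv_folds"))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  acc <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    model <- train_subtype_classifier(beta[, tr, drop = FALSE], labels[tr],
                                      signatures, n_trees = n_trees,
                                      seed = derive_seed(seed, paste0("f", f)))
    res <- classify(model, beta[, !tr, drop = FALSE])
    classification_accuracy(res, setNames(labels, colnames(beta)))
  }, numeric(1))
  list(fold_accuracy = acc, mean_accuracy = mean(acc))
}

#' Per-subtype counts and percentages of a classified cohort
#'
#' @param results output of [classify()] (uses the final `subtype` label,
#'   so gcimp_intermediate appears as its own row when present)
#' @return data.frame: subtype, n, percent (two decimals, half-up)
#' @export
cohort_summary <- function(results) {
  if (is.data.frame(results)) labels <- results$subtype
  else labels <- as.character(results)
  if (!length(labels)) stop("empty classification results")
  tab <- table(labels)
  out <- data.frame(subtype = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- percent_of(out$n, sum(out$n))
  out[order(-out$n), , drop = FALSE]
}
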