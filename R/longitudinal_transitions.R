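# Patient-level aggregation of fragment classifications and tabulation of
# primary -> first-recurrence subtype transitions.

# progression ordering used for tie-breaking within the G-CIMP spectrum;
# labels outside the spectrum rank below it and fall back to alphabetical
PROGRESSION_ORDER <- c("gcimp_high", "gcimp_intermediate", "gcimp_low")

#' Aggregate fragment labels for one patient-surgery to a single label
#'
#' Modal label; ties are broken toward the more progressed label under the
#' ordering gcimp_high < gcimp_intermediate < gcimp_low. Ties among labels
#' outside that spectrum are broken alphabetically (deterministic).
#'
#' @param labels character vector of fragment subtype labels
#' @return single label
#' @export
aggregate_patient_label <- function(labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop("no fragment labels to aggregate")
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  rank <- match(top, PROGRESSION_ORDER)
  if (any(!is.na(rank))) return(top[which.max(rank)])
  sort(top)[1]
}

categorize_transition <- function(primary, recurrence, second = NA) {
  if (primary == "gcimp_high" && recurrence == "gcimp_low") return("change")
  if (primary == "gcimp_intermediate" || recurrence == "gcimp_intermediate")
    return("intermediate_change")
  # still gcimp_high through first recurrence but gcimp_low by the second
  if (primary == "gcimp_high" && recurrence == "gcimp_high" &&
      !is.na(second) && second == "gcimp_low")
    return("intermediate_change")
  if (primary == recurrence) return("no_change")
  "other"
}

#' Build the patient-level transition table
#'
#' Aggregates fragment classifications to one label per patient-timepoint
#' and categorizes each patient with both a primary and a first-recurrence
#' surgery: `no_change` (same label), `change` (gcimp_high to gcimp_low),
#' `intermediate_change` (either endpoint gcimp_intermediate, or gcimp_low
#' reached at second recurrence), `other` for remaining label pairs.
#' Patients lacking either timepoint are excluded and listed.
#'
#' @param sheet sample sheet linking sample_id to patient_id/timepoint
#' @param results [classify()] output for the same samples
#' @return list: `table` (patient_id, primary_label, recurrence_label,
#'   second_recurrence_label, category), `excluded` (patient IDs missing a
#'   timepoint)
#' @export
build_transition_table <- function(sheet, results) {
  validate_sample_sheet(sheet)
  lab <- setNames(results$subtype, results$sample_id)
  miss <- setdiff(sheet$sample_id, names(lab))
  if (length(miss))
    stop("sample(s) missing classification: ", paste(head(miss, 5),
                                                     collapse = ", "))
  sheet$label <- lab[sheet$sample_id]
  agg <- function(tp) {
    sub <- sheet[sheet$timepoint == tp, , drop = FALSE]
    if (!nrow(sub)) return(setNames(character(0), character(0)))
    vapply(split(sub$label, sub$patient_id), aggregate_patient_label,
           character(1))
  }
  prim <- agg("primary")
  rec1 <- agg("first_recurrence")
  rec2 <- agg("second_recurrence")
  evaluable <- intersect(names(prim), names(rec1))
  excluded <- setdiff(unique(sheet$patient_id), evaluable)
  tab <- data.frame(
    patient_id = evaluable,
    primary_label = prim[evaluable],
    recurrence_label = rec1[evaluable],
    second_recurrence_label = unname(rec2[evaluable]),
    stringsAsFactors = FALSE)
  tab$category <- mapply(categorize_transition, tab$primary_label,
                         tab$recurrence_label, tab$second_recurrence_label)
  rownames(tab) <- NULL
  list(table = tab, excluded = excluded)
}

#' Summarize transition categories among gcimp_high-primary patients
#'
#' @param transitions output of [build_transition_table()] (or its `table`)
#' @param percent_digits decimals for the printed percentages (default 0,
#'   whole numbers)
#' @return data.frame: category, n, percent, over patients whose primary
#'   label is gcimp_high
#' @export
transition_summary <- function(transitions, percent_digits = 0) {
  tab <- if (is.data.frame(transitions)) transitions else transitions$table
  if (!nrow(tab)) stop("empty transition table")
  hi <- tab[tab$primary_label == "gcimp_high", , drop = FALSE]
  cats <- c("no_change", "intermediate_change", "change", "other")
  n <- vapply(cats, function(cc) sum(hi$category == cc), integer(1))
  out <- data.frame(category = cats, n = n, stringsAsFactors = FALSE)
  out$percent <- percent_of(out$n, max(nrow(hi), 1L), percent_digits)
  out$of_total <- nrow(hi)
  rownames(out) <- NULL
  out
}
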