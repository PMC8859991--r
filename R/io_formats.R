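# Delimited-text IO for every table the pipeline touches. TSV is the
# canonical interchange format; beta matrices are plain numeric matrices
# (probes x samples) with dimnames, sample sheets and annotations are
# data.frames. All readers validate strictly so downstream code can assume
# well-formed inputs.

TIMEPOINT_LEVELS <- c("primary", "first_recurrence", "second_recurrence")
GRADE_LEVELS     <- c("II", "III", "IV", "unknown")
IDH_LEVELS       <- c("mutant", "wildtype", "unknown")
CODEL_LEVELS     <- c("codel", "non_codel", "unknown")
YESNO_LEVELS     <- c("yes", "no", "unknown")
CGI_LEVELS       <- c("island", "shore", "shelf", "open_sea")
CHROM_LEVELS     <- c(paste0("chr", 1:22), "chrX", "chrY")

SUBTYPE_LEVELS <- c("codel", "gcimp_high", "gcimp_low",
                    "classic_like", "mesenchymal_like", "lgm6_gbm", "pa_like")
IDH_MUT_SUBTYPES <- c("codel", "gcimp_high", "gcimp_low")
IDH_WT_SUBTYPES  <- c("classic_like", "mesenchymal_like", "lgm6_gbm", "pa_like")

SIGNATURE_NAMES <- c("macro_1300", "idh_mut_1308", "idh_mut_subtype_163",
                     "idh_wt_914", "stemness_219")

#' Validate a beta-value matrix
#'
#' Checks that `x` is a numeric matrix of methylation fractions with unique
#' probe rownames and sample colnames, and that all non-missing values lie
#' in \[0, 1\]. Missing values are permitted.
#'
#' @param x numeric matrix, probes in rows, samples in columns
#' @return `x`, invisibly, if valid; otherwise an error
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate probe IDs in beta matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample IDs in beta matrix")
  v <- x[!is.na(x)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("beta values outside [0,1]")
  invisible(x)
}

#' Read a beta-value matrix from delimited text
#'
#' First column holds probe IDs, header row holds sample IDs. Empty cells
#' become missing values; any non-missing value outside \[0, 1\] or a
#' non-numeric cell is an error.
#'
#' @param path file path
#' @param delimiter field delimiter (default tab)
#' @return validated numeric matrix (probes x samples)
#' @export
read_beta_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          na.strings = c("", "NA"), data.table = FALSE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("beta matrix file needs a probe column plus samples")
  probes <- dt[[1]]
  if (anyDuplicated(probes)) stop("duplicate probe IDs in ", path)
  if (anyDuplicated(names(dt)[-1])) stop("duplicate sample IDs in ", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))
    # locate the first offending cell for the error report
    col <- names(dt)[-1][bad[1]]
    vals <- dt[[bad[1] + 1]]
    row <- which(is.na(suppressWarnings(as.numeric(vals))) & !is.na(vals))[1]
    stop(sprintf("non-numeric beta value at probe '%s', sample '%s'",
                 probes[row], col))
  }
  rownames(m) <- probes
  storage.mode(m) <- "double"
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix to delimited text
#'
#' Values are printed with six decimals so that a write/read round trip
#' reproduces the matrix at that precision.
#'
#' @param x beta matrix
#' @param path output path
#' @param delimiter field delimiter (default tab)
#' @export
write_beta_matrix <- function(x, path, delimiter = "\t") {
  validate_beta_matrix(x)
  df <- data.frame(probe_id = rownames(x),
                   formatC(x, format = "f", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[df == "NA"] <- NA
  colnames(df) <- c("probe_id", colnames(x))
  data.table::fwrite(df, path, sep = delimiter, na = "", quote = FALSE)
  invisible(path)
}

normalize_enum <- function(x, levels, field) {
  y <- tolower(trimws(as.character(x)))
  y[y == "" | is.na(y)] <- "unknown"
  ok <- y %in% tolower(levels)
  if (!all(ok))
    stop(sprintf("invalid %s value(s): %s", field,
                 paste(unique(x[!ok]), collapse = ", ")))
  levels[match(y, tolower(levels))]
}

SHEET_REQUIRED <- c("sample_id", "patient_id", "timepoint", "fragment_index")

#' Validate a sample sheet
#'
#' @param sheet data.frame of per-fragment clinical/longitudinal metadata
#' @return `sheet`, invisibly
#' @export
validate_sample_sheet <- function(sheet) {
  miss <- setdiff(SHEET_REQUIRED, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id")
  key <- paste(sheet$patient_id, sheet$timepoint, sheet$fragment_index)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, timepoint, fragment_index) key: ",
         key[duplicated(key)][1])
  if (any(sheet$fragment_index < 1)) stop("fragment_index must be >= 1")
  if (!is.null(sheet$survival_time) &&
      any(sheet$survival_time < 0, na.rm = TRUE))
    stop("negative survival_time")
  invisible(sheet)
}

#' Read a sample sheet from delimited text
#'
#' Enumerated fields (timepoint, grade, idh_status, codel_status, radiation,
#' tmz, sex) are normalized case-insensitively; missing entries become
#' `"unknown"`. The (patient_id, timepoint, fragment_index) key must be
#' unique.
#'
#' @param path file path
#' @param delimiter field delimiter
#' @return data.frame sample sheet
#' @export
read_sample_sheet <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  sheet <- data.table::fread(path, sep = delimiter, header = TRUE,
                             na.strings = c("", "NA"), data.table = FALSE)
  miss <- setdiff(SHEET_REQUIRED, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  sheet$timepoint <- normalize_enum(sheet$timepoint, TIMEPOINT_LEVELS,
                                    "timepoint")
  for (col in c("grade", "idh_status", "codel_status", "radiation", "tmz")) {
    lv <- switch(col, grade = GRADE_LEVELS, idh_status = IDH_LEVELS,
                 codel_status = CODEL_LEVELS, YESNO_LEVELS)
    if (col %in% names(sheet)) {
      if (col == "grade") {
        y <- toupper(trimws(as.character(sheet[[col]])))
        y[y == "" | is.na(y)] <- "UNKNOWN"
        if (!all(y %in% toupper(GRADE_LEVELS)))
          stop("invalid grade value(s)")
        sheet[[col]] <- GRADE_LEVELS[match(y, toupper(GRADE_LEVELS))]
      } else {
        sheet[[col]] <- normalize_enum(sheet[[col]], lv, col)
      }
    }
  }
  if ("survival_event" %in% names(sheet))
    sheet$survival_event <- as.logical(sheet$survival_event)
  validate_sample_sheet(sheet)
  sheet
}

#' Read a probe annotation table
#'
#' Requires chromosome, position and CGI-relation columns; boolean feature
#' flags (enhancer, bivalent, motif hit columns prefixed `motif_`) are
#' optional and default to FALSE when absent or missing. CGI relation is
#' normalized case-insensitively to island/shore/shelf/open_sea; shores are
#' the 2 kb flanks of islands by convention.
#'
#' @param path file path
#' @param delimiter field delimiter
#' @return data.frame keyed by unique probe_id
#' @export
read_probe_annotation <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- data.table::fread(path, sep = delimiter, header = TRUE,
                           na.strings = c("", "NA"), data.table = FALSE)
  req <- c("probe_id", "chromosome", "position", "cgi_relation")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe_id in annotation")
  if (!all(ann$chromosome %in% CHROM_LEVELS))
    stop("unknown chromosome label(s): ",
         paste(unique(setdiff(ann$chromosome, CHROM_LEVELS)), collapse = ", "))
  cgi <- tolower(gsub("[ .-]", "_", trimws(as.character(ann$cgi_relation))))
  cgi[cgi == "opensea"] <- "open_sea"
  if (!all(cgi %in% CGI_LEVELS))
    stop("unknown cgi_relation value(s): ",
         paste(unique(ann$cgi_relation[!cgi %in% CGI_LEVELS]), collapse = ", "))
  ann$cgi_relation <- cgi
  for (col in c("enhancer", "bivalent",
                grep("^motif_", names(ann), value = TRUE))) {
    if (col %in% names(ann)) {
      v <- ann[[col]]
      if (!is.logical(v)) v <- as.logical(v)
      v[is.na(v)] <- FALSE
      ann[[col]] <- v
    } else {
      ann[[col]] <- FALSE
    }
  }
  ann
}

#' Read a signature probe set
#'
#' One probe ID per line; a second tab-separated column of numeric weights
#' is required for the stemness set and forbidden meaning ignored otherwise.
#' Repeated probes are deduplicated (first occurrence kept) with a warning.
#'
#' @param path file path
#' @param name signature name, one of
#'   `r paste(SIGNATURE_NAMES, collapse = ", ")`
#' @return list with `name`, `probe_ids`, and `weights` (stemness only)
#' @export
read_signature_set <- function(path, name = c("macro_1300", "idh_mut_1308",
                                              "idh_mut_subtype_163",
                                              "idh_wt_914", "stemness_219")) {
  name <- match.arg(name)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signature file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  weights <- NULL
  if (name == "stemness_219") {
    if (any(lengths(parts) < 2))
      stop("stemness signature requires a weight column")
    weights <- as.numeric(vapply(parts, `[[`, character(1), 2))
    if (anyNA(weights)) stop("non-numeric stemness weight")
  }
  if (anyDuplicated(ids)) {
    warning("duplicated probe ID(s) in signature '", name, "'; keeping first")
    keep <- !duplicated(ids)
    ids <- ids[keep]
    if (!is.null(weights)) weights <- weights[keep]
  }
  sig <- list(name = name, probe_ids = ids)
  if (!is.null(weights)) sig$weights <- setNames(weights, ids)
  sig
}

#' Write a signature probe set
#'
#' @param sig signature list as returned by [read_signature_set()]
#' @param path output path
#' @export
write_signature_set <- function(sig, path) {
  if (!is.null(sig$weights)) {
    writeLines(paste(sig$probe_ids,
                     formatC(unname(sig$weights), format = "g", digits = 15),
                     sep = "\t"), path)
  } else {
    writeLines(sig$probe_ids, path)
  }
  invisible(path)
}

#' Write a generic results table as TSV
#'
#' @param df data.frame
#' @param path output path
#' @export
write_table_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' @param x named list of scalars/vectors
#' @param path output path
#' @export
write_run_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
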