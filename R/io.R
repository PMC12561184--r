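#' Construct a survival cohort
#'
#' Bundles per-subject follow-up (`time`, `event`), clinical covariates,
#' and a gene x sample expression matrix that may include normal-tissue
#' samples (used only by the differential-expression filter). Every tumor
#' subject with a survival row must have an expression column.
#'
#' @param subject_id unique subject ids (tumor subjects with follow-up).
#' @param time positive follow-up times, in the unit named by `time_unit`.
#' @param event 1 = death observed, 0 = censored.
#' @param covariates data.frame with numeric `age` (years) and ordinal
#'   `stage`.
#' @param expression gene x sample numeric matrix; columns must cover
#'   `subject_id` and may add normal samples.
#' @param tissue named vector (`tumor`/`normal`) over the expression
#'   columns; defaults to all-tumor.
#' @param time_unit declared unit of `time` (no silent conversion is ever
#'   applied downstream).
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(subject_id, time, event, covariates = NULL,
                            expression = NULL, tissue = NULL,
                            time_unit = "months") {
  if (anyDuplicated(subject_id)) stop("duplicated subject ids")
  n <- length(subject_id)
  if (length(time) != n || length(event) != n)
    stop("time/event length must match subject_id")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and > 0 (offending rows: ",
         paste(utils::head(which(!is.finite(time) | time <= 0), 5), collapse = ", "), ")")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per subject")
  }
  if (!is.null(expression)) {
    if (!is.matrix(expression) || is.null(rownames(expression)) ||
        is.null(colnames(expression)))
      stop("expression must be a named gene x sample matrix")
    miss <- setdiff(subject_id, colnames(expression))
    if (length(miss))
      stop("expression lacks columns for subjects: ", paste(miss, collapse = ", "))
    if (is.null(tissue))
      tissue <- stats::setNames(rep("tumor", ncol(expression)), colnames(expression))
    if (!all(colnames(expression) %in% names(tissue)))
      stop("tissue labels must cover every expression column")
    tissue <- tissue[colnames(expression)]
    if (!all(tissue %in% c("tumor", "normal")))
      stop("tissue labels must be 'tumor' or 'normal'")
  }
  structure(list(subject_id = subject_id, time = as.numeric(time),
                 event = as.integer(event), covariates = covariates,
                 expression = expression, tissue = tissue,
                 time_unit = time_unit),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat("survival_cohort:", length(x$subject_id), "subjects,",
      sum(x$event), "events, time in", x$time_unit, "\n")
  if (!is.null(x$expression))
    cat("  expression:", nrow(x$expression), "genes x", ncol(x$expression),
        "samples (", sum(x$tissue == "normal"), "normal )\n")
  invisible(x)
}

#' Read survival follow-up from CSV
#'
#' Mandatory columns: `subject_id`, `time`, `event`; any further columns
#' are kept as covariates. Non-positive times and events outside
#' `{0, 1}` are rejected with the offending rows named.
#'
#' @param path CSV path.
#' @param time_unit declared unit of the `time` column.
#' @return data.frame of validated survival rows.
#' @export
read_survival <- function(path, time_unit = "months") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "time", "event"), names(df))
  if (length(miss)) stop("survival file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad)) stop("survival times must be > 0; offending row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (!all(df$event %in% c(0, 1))) stop("event column must be 0/1")
  attr(df, "time_unit") <- time_unit
  df
}

#' Read a gene x sample expression matrix from CSV
#'
#' First column holds gene ids, remaining columns one sample each.
#'
#' @param path CSV path.
#' @return numeric matrix with gene row names.
#' @export
read_expression <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- df[[1]]
  m
}

#' Read a cell-type x subject infiltration fraction table
#'
#' @param path CSV path; first column cell types, remaining columns
#'   subjects.
#' @return numeric matrix of fractions/scores.
#' @export
read_fractions <- function(path) {
  m <- read_expression(path)
  if (any(!is.finite(m))) stop("non-finite infiltration values in ", path)
  m
}

#' Write a set of result tables with a sidecar log
#'
#' Each element of `tables` (a named list of data.frames) is written as
#' `<name>.csv` under `path`; a `report_log.txt` sidecar records row
#' counts. Numeric columns are serialized at 17 significant digits so a
#' write/read round trip restores them bit-identically.
#'
#' @param tables named list of data.frames.
#' @param path output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, path) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  log <- character()
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    tab <- tables[[nm]]
    for (j in seq_along(tab))                  # 17 digits: lossless round trip
      if (is.double(tab[[j]])) tab[[j]] <- sprintf("%.17g", tab[[j]])
    utils::write.csv(tab, f, row.names = FALSE)
    out <- c(out, f)
    log <- c(log, sprintf("%s: %d rows, %d cols", nm,
                          nrow(tables[[nm]]), ncol(tables[[nm]])))
  }
  writeLines(log, file.path(path, "report_log.txt"))
  invisible(out)
}

#' Reference-anchored location-scale batch adjustment
#'
#' Per gene, each non-reference batch is standardized to zero mean and
#' unit variance and mapped to the reference batch's gene mean and SD; the
#' reference batch passes through unchanged. This is a deliberate,
#' transparently named replacement for empirical-Bayes batch correction:
#' the downstream score (a fixed weighted sum compared against its
#' within-cohort median) is invariant to the difference for the designs
#' handled here. The map is idempotent -- once batch moments match the
#' reference, applying it again changes nothing.
#'
#' A gene with zero variance inside a non-reference batch cannot be
#' rescaled; it falls back to a mean shift only, with a warning.
#'
#' @param x gene x sample numeric matrix.
#' @param batch batch label per column of `x`.
#' @param reference label of the reference batch (left unchanged); every
#'   gene must have non-zero variance there.
#' @return The adjusted matrix, same dimensions as `x`.
#' @export
adjust_batches <- function(x, batch, reference) {
  stopifnot(is.matrix(x), length(batch) == ncol(x))
  batches <- unique(batch)
  if (length(batches) < 2) stop("need >= 2 batches")
  if (!reference %in% batches) stop("reference batch not present: ", reference)
  ref_cols <- batch == reference
  ref_mean <- rowMeans(x[, ref_cols, drop = FALSE])
  ref_sd <- apply(x[, ref_cols, drop = FALSE], 1, stats::sd)
  if (any(ref_sd == 0))
    stop("zero-variance gene(s) in the reference batch: ",
         paste(utils::head(rownames(x)[ref_sd == 0], 5), collapse = ", "))
  out <- x
  for (b in setdiff(batches, reference)) {
    cols <- batch == b
    m <- rowMeans(x[, cols, drop = FALSE])
    s <- apply(x[, cols, drop = FALSE], 1, stats::sd)
    flat <- s == 0 | is.na(s)
    if (any(flat)) {
      warning("zero-variance gene(s) in batch ", b, "; mean-shift only for: ",
              paste(utils::head(rownames(x)[flat], 5), collapse = ", "))
      s[flat] <- ref_sd[flat]                 # scale map collapses to shift
    }
    out[, cols] <- (x[, cols, drop = FALSE] - m) / s * ref_sd + ref_mean
  }
  out
}
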