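#' @keywords internal
"_PACKAGE"

NPX_TIMEPOINTS <- c("D0", "D5", "DT", "PD", "LT")

#' Construct a longitudinal NPX matrix
#'
#' The central container for relative protein abundance (NPX, a log2-like
#' unit) measured on serial plasma samples. Rows are proteins, columns are
#' samples; each sample belongs to one patient and carries one time-point
#' label (`D0` baseline, `D5` early on-treatment, `DT` during treatment,
#' `PD` progression, `LT` last sampling time). Patients may carry a
#' response-group label (`GoR` good responder / `PoR` poor responder /
#' `unknown`) used by the supervised selection step.
#'
#' @param values numeric matrix, proteins x samples, with unique dimnames.
#'   Missing cells are allowed and preserved.
#' @param sample_meta data.frame with columns `sample_id`, `patient_id`,
#'   `timepoint` and optionally `order` (collection order within patient)
#'   and `lt` (logical, sample additionally plays the last-time role).
#' @param patient_meta data.frame with columns `patient_id` and `group`
#'   (`GoR`, `PoR` or `unknown`). Defaults to all-`unknown`.
#' @return An object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, sample_meta, patient_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (proteins x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have protein row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("protein ids must be unique; duplicated: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  req <- c("sample_id", "patient_id", "timepoint")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss)) stop("sample_meta missing column(s): ", paste(miss, collapse = ", "))
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (anyDuplicated(sample_meta$sample_id))
    stop("sample_meta has duplicated sample ids")
  if (!setequal(sample_meta$sample_id, colnames(values)))
    stop("sample_meta sample ids do not match the columns of `values`")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  bad_tp <- setdiff(unique(sample_meta$timepoint), NPX_TIMEPOINTS)
  if (length(bad_tp))
    stop("unknown time-point label(s): ", paste(bad_tp, collapse = ", "),
         " (allowed: ", paste(NPX_TIMEPOINTS, collapse = ", "), ")")
  dup_pt_tp <- duplicated(sample_meta[, c("patient_id", "timepoint")])
  if (any(dup_pt_tp)) {
    off <- sample_meta[dup_pt_tp, ]
    stop("more than one sample for (patient, timepoint): ",
         paste(paste0(off$patient_id, "/", off$timepoint), collapse = ", "))
  }
  if (is.null(sample_meta$order))
    sample_meta$order <- match(sample_meta$timepoint, NPX_TIMEPOINTS)
  if (is.null(sample_meta$lt))
    sample_meta$lt <- sample_meta$timepoint == "LT"
  sample_meta$lt <- sample_meta$lt | sample_meta$timepoint == "LT"
  if (is.null(patient_meta)) {
    patient_meta <- data.frame(patient_id = unique(sample_meta$patient_id),
                               group = "unknown", stringsAsFactors = FALSE)
  }
  patient_meta <- as.data.frame(patient_meta, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "group") %in% names(patient_meta)))
    stop("patient_meta needs columns patient_id, group")
  if (anyDuplicated(patient_meta$patient_id))
    stop("patient_meta has duplicated patient ids")
  bad_g <- setdiff(unique(patient_meta$group), c("GoR", "PoR", "unknown"))
  if (length(bad_g)) stop("unknown response group(s): ", paste(bad_g, collapse = ", "))
  orphan <- setdiff(sample_meta$patient_id, patient_meta$patient_id)
  if (length(orphan))
    stop("samples reference patients absent from patient_meta: ",
         paste(orphan, collapse = ", "))
  structure(list(values = values, sample_meta = sample_meta,
                 patient_meta = patient_meta),
            class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  tp <- table(factor(x$sample_meta$timepoint, levels = NPX_TIMEPOINTS))
  cat("npx_matrix: ", nrow(x$values), " proteins x ", ncol(x$values),
      " samples from ", nrow(x$patient_meta), " patients\n", sep = "")
  cat("  samples per time point:",
      paste(names(tp)[tp > 0], tp[tp > 0], sep = "=", collapse = ", "), "\n")
  if (any(x$sample_meta$lt))
    cat("  LT role assigned to", sum(x$sample_meta$lt), "samples\n")
  grp <- table(x$patient_meta$group)
  cat("  patient groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  if (anyNA(x$values))
    cat("  missing cells:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

#' Columns of an NPX matrix at a given time point
#'
#' `LT` resolves through the last-time role flag, so a `PD` sample assigned
#' as last time by [assign_lt()] is returned for `tp = "LT"`.
#'
#' @param m an [npx_matrix()].
#' @param tp a single time-point label.
#' @return character vector of sample ids (possibly empty).
#' @export
samples_at <- function(m, tp) {
  stopifnot(inherits(m, "npx_matrix"), length(tp) == 1L)
  sm <- m$sample_meta
  if (tp == "LT") sm$sample_id[sm$lt] else sm$sample_id[sm$timepoint == tp]
}

#' Read a long-format NPX table
#'
#' Expects a CSV with columns `sample_id`, `patient_id`, `timepoint`,
#' `protein_id`, `npx` and optionally `group` (per-patient response label)
#' and `order` (collection order). Duplicate (sample, protein) measurements
#' are rejected naming the offending pair; missing cells stay missing.
#'
#' @param path CSV file path.
#' @return An [npx_matrix()].
#' @export
read_npx_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty NPX file: ", path)
  req <- c("sample_id", "patient_id", "timepoint", "protein_id", "npx")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("NPX file missing column(s): ", paste(miss, collapse = ", "))
  dup <- duplicated(df[, c("sample_id", "protein_id")])
  if (any(dup)) {
    off <- df[dup, ][1L, ]
    stop("duplicated measurement for sample ", off$sample_id,
         ", protein ", off$protein_id)
  }
  proteins <- unique(df$protein_id)
  samples <- unique(df$sample_id)
  vals <- matrix(NA_real_, length(proteins), length(samples),
                 dimnames = list(proteins, samples))
  vals[cbind(match(df$protein_id, proteins), match(df$sample_id, samples))] <- df$npx
  keep <- c("sample_id", "patient_id", "timepoint",
            intersect(c("order", "lt"), names(df)))
  sm <- unique(df[, keep, drop = FALSE])
  if (anyDuplicated(sm$sample_id))
    stop("a sample id maps to more than one (patient, timepoint)")
  pm <- NULL
  if ("group" %in% names(df)) {
    pm <- unique(df[, c("patient_id", "group")])
    if (anyDuplicated(pm$patient_id))
      stop("a patient id maps to more than one response group")
  }
  npx_matrix(vals, sm, pm)
}

#' Write an NPX matrix in long format
#'
#' Inverse of [read_npx_long()]; missing cells are omitted from the output
#' so a write/read round trip preserves the missingness pattern.
#'
#' @param m an [npx_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_npx_long <- function(m, path) {
  stopifnot(inherits(m, "npx_matrix"))
  sm <- m$sample_meta
  grp <- m$patient_meta$group[match(sm$patient_id, m$patient_meta$patient_id)]
  long <- data.frame(
    sample_id = rep(colnames(m$values), each = nrow(m$values)),
    patient_id = rep(sm$patient_id, each = nrow(m$values)),
    timepoint = rep(sm$timepoint, each = nrow(m$values)),
    order = rep(sm$order, each = nrow(m$values)),
    lt = rep(sm$lt, each = nrow(m$values)),
    group = rep(grp, each = nrow(m$values)),
    protein_id = rep(rownames(m$values), times = ncol(m$values)),
    npx = as.vector(m$values),
    stringsAsFactors = FALSE)
  long <- long[!is.na(long$npx), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Assign the last-time (LT) sampling role
#'
#' For each patient the progression (`PD`) sample, if present, otherwise the
#' chronologically last collected sample, is tagged with the additional `LT`
#' role. The original time-point label is kept, so baseline-vs-last
#' contrasts and full four-point trajectories remain constructible from the
#' same object.
#'
#' @param m an [npx_matrix()].
#' @return The matrix with the `lt` flag set (exactly one per patient).
#' @export
assign_lt <- function(m) {
  stopifnot(inherits(m, "npx_matrix"))
  sm <- m$sample_meta
  sm$lt <- FALSE
  for (pt in unique(m$patient_meta$patient_id)) {
    idx <- which(sm$patient_id == pt)
    if (length(idx) == 0L) stop("patient with zero samples: ", pt)
    pd <- idx[sm$timepoint[idx] == "PD"]
    pick <- if (length(pd)) pd[1L] else idx[which.max(sm$order[idx])]
    sm$lt[pick] <- TRUE
  }
  m$sample_meta <- sm
  m
}
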