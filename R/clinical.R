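#' Half-up rounding for printed percentages
#'
#' Trial tables round percentages half-up (36.35 -> 36.4), unlike base
#' [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' RECIST 1.1 time-point response from target-lesion sums
#'
#' Classifies a single assessment: new lesions or a >= 20% increase of the
#' target-lesion sum over the nadir (the smallest prior sum, baseline
#' included) is `PD`; complete disappearance (`sum = 0`) is `CR`; a
#' >= 30% decrease from baseline is `PR`; anything in between is `SD`. A
#' zero nadir with a non-zero current sum cannot be fractionally compared
#' and is flagged `NE`.
#'
#' @param baseline_sum baseline target-lesion sum in mm (> 0).
#' @param assessment_sum current sum in mm (>= 0).
#' @param nadir_sum smallest prior sum in mm; defaults to the baseline.
#' @param new_lesion any new lesion at this assessment?
#' @return one of `"CR"`, `"PR"`, `"SD"`, `"PD"`, `"NE"`.
#' @export
classify_response <- function(baseline_sum, assessment_sum,
                              nadir_sum = baseline_sum, new_lesion = FALSE) {
  if (baseline_sum <= 0) stop("baseline sum must be > 0 for an evaluable patient")
  if (assessment_sum < 0 || nadir_sum < 0) stop("lesion sums must be >= 0")
  if (isTRUE(new_lesion)) return("PD")
  if (assessment_sum == 0) return("CR")
  if (nadir_sum == 0) return("NE")                 # regrowth after CR: not comparable
  if ((assessment_sum - nadir_sum) / nadir_sum >= 0.20) return("PD")
  if ((baseline_sum - assessment_sum) / baseline_sum >= 0.30) return("PR")
  "SD"
}

#' Best overall response across assessments
#'
#' Best response along the ordering `CR > PR > SD > PD`, considering
#' assessments up to and including the first progression (appending
#' assessments after the first `PD` never changes the call). With no
#' assessment the patient is not evaluable (`NE`).
#'
#' @param responses character vector of per-assessment calls in
#'   chronological order.
#' @return single best response, or `"NE"`.
#' @export
best_overall_response <- function(responses) {
  responses <- responses[!is.na(responses)]
  if (length(responses) == 0) return("NE")
  first_pd <- match("PD", responses)
  if (!is.na(first_pd)) responses <- responses[seq_len(first_pd)]
  ord <- c(CR = 1, PR = 2, SD = 3, PD = 4, NE = 5)
  names(ord)[min(ord[responses])]
}

#' Call per-patient responses from an assessment table
#'
#' Works through a long table of target-lesion sums (one row per patient
#' and visit; `month = 0` is baseline), classifying every post-baseline
#' assessment against the running nadir and deriving the best overall
#' response, the best percent change from baseline, and the duration of
#' disease control (months from baseline to the last assessment at or
#' before progression).
#'
#' @param assessments data.frame with columns `patient`, `month`,
#'   `sum_mm`, optional `new_lesion` (logical) and `dose_mg`.
#' @return data.frame: patient, dose_mg, baseline_mm, best_response,
#'   best_pct_change, duration_months.
#' @export
call_responses <- function(assessments) {
  req <- c("patient", "month", "sum_mm")
  miss <- setdiff(req, names(assessments))
  if (length(miss)) stop("assessment table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(assessments$new_lesion)) assessments$new_lesion <- FALSE
  if (is.null(assessments$dose_mg)) assessments$dose_mg <- NA_real_
  out <- lapply(split(assessments, assessments$patient), function(d) {
    d <- d[order(d$month), , drop = FALSE]
    base <- d$sum_mm[d$month == 0]
    if (length(base) != 1)
      stop("patient ", d$patient[1], " needs exactly one baseline (month 0) row")
    post <- d[d$month > 0, , drop = FALSE]
    if (nrow(post) == 0)
      return(data.frame(patient = d$patient[1], dose_mg = d$dose_mg[1],
                        baseline_mm = base, best_response = "NE",
                        best_pct_change = NA_real_, duration_months = NA_real_))
    nadir <- base
    calls <- character(nrow(post))
    for (i in seq_len(nrow(post))) {
      calls[i] <- classify_response(base, post$sum_mm[i], nadir,
                                    isTRUE(post$new_lesion[i]))
      nadir <- min(nadir, post$sum_mm[i])
    }
    bor <- best_overall_response(calls)
    first_pd <- match("PD", calls)
    ctrl <- if (is.na(first_pd)) post$month else post$month[seq_len(first_pd)]
    data.frame(patient = d$patient[1], dose_mg = d$dose_mg[1],
               baseline_mm = base, best_response = bor,
               best_pct_change = 100 * (min(post$sum_mm) - base) / base,
               duration_months = max(ctrl))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trial efficacy table (ORR / DCR)
#'
#' Objective response rate = CR or PR as best response; disease control
#' rate = CR, PR or SD. Percentages are rounded half-up to one decimal.
#'
#' @param records data.frame with a `best_response` column (e.g. from
#'   [call_responses()]); `NE` patients count in the denominator.
#' @return list with `n`, counts per category, `orr_pct`, `dcr_pct`.
#' @export
efficacy_table <- function(records) {
  br <- records$best_response
  if (is.null(br)) br <- as.character(records)
  n <- length(br)
  if (n == 0) stop("no records")
  counts <- table(factor(br, levels = c("CR", "PR", "SD", "PD", "NE")))
  orr <- sum(counts[c("CR", "PR")]) / n
  dcr <- sum(counts[c("CR", "PR", "SD")]) / n
  list(n = n, counts = counts,
       orr_pct = round_half_up(100 * orr, 1),
       dcr_pct = round_half_up(100 * dcr, 1))
}

#' Stratify good vs poor responders
#'
#' `CR` and `PR` patients are good responders (GoR); `SD` patients are
#' GoR when disease control lasted at least `sd_duration_threshold`
#' months (inclusive) and poor responders (PoR) below it; `PD` patients
#' are PoR. An `SD` patient without a duration cannot be stratified and
#' is labelled `unknown` with a warning.
#'
#' @param records data.frame with `best_response` and `duration_months`.
#' @param sd_duration_threshold months of disease control an SD patient
#'   needs for GoR.
#' @return character vector of labels, named by patient when available.
#' @export
stratify_gor_por <- function(records, sd_duration_threshold = 4) {
  br <- records$best_response
  dur <- records$duration_months
  lab <- rep("unknown", length(br))
  lab[br %in% c("CR", "PR")] <- "GoR"
  lab[br == "PD"] <- "PoR"
  sd_idx <- which(br == "SD")
  for (i in sd_idx) {
    if (is.na(dur[i])) {
      warning("SD patient without duration cannot be stratified: ",
              records$patient[i])
    } else {
      lab[i] <- if (dur[i] >= sd_duration_threshold) "GoR" else "PoR"
    }
  }
  if (!is.null(records$patient)) names(lab) <- records$patient
  lab
}

#' Summarize treatment-emergent adverse events
#'
#' Builds the standard safety table from a per-event listing: for every
#' term, each patient is counted once at their worst grade (duplicate
#' (patient, term) rows merge to the worst grade); the `Any` row counts
#' patients with at least one event overall and, per grade column,
#' patients with at least one term whose worst grade falls in that
#' column. Grades 3-5 are pooled into a `G3+` column as safety tables of
#' small trials conventionally do.
#'
#' @param listings data.frame with columns `patient`, `term`, `grade`
#'   (1-5).
#' @param n_patients denominator for percentages (enrolled patients);
#'   defaults to the number of distinct patients in the listing.
#' @return data.frame with one row per term plus a leading `Any` row:
#'   term, n_any, pct_any, n_g1, pct_g1, n_g2, pct_g2, n_g3plus,
#'   pct_g3plus.
#' @export
teae_summary <- function(listings, n_patients = NULL) {
  req <- c("patient", "term", "grade")
  miss <- setdiff(req, names(listings))
  if (length(miss)) stop("listing missing column(s): ", paste(miss, collapse = ", "))
  if (!all(listings$grade %in% 1:5)) stop("grades must be integers 1..5")
  if (is.null(n_patients)) n_patients <- length(unique(listings$patient))
  if (nrow(listings) == 0)
    return(data.frame(term = "Any", n_any = 0, pct_any = 0, n_g1 = 0,
                      pct_g1 = 0, n_g2 = 0, pct_g2 = 0, n_g3plus = 0,
                      pct_g3plus = 0, stringsAsFactors = FALSE))
  worst <- stats::aggregate(grade ~ patient + term, data = listings, FUN = max)
  gcol <- function(g) ifelse(g >= 3, "g3plus", paste0("g", g))
  worst$col <- gcol(worst$grade)
  one_term <- function(d) {
    counts <- c(any = nrow(d),
                g1 = sum(d$col == "g1"), g2 = sum(d$col == "g2"),
                g3plus = sum(d$col == "g3plus"))
  }
  terms <- sort(unique(worst$term))
  rows <- t(vapply(terms, function(tm) one_term(worst[worst$term == tm, ]),
                   numeric(4)))
  any_row <- c(any = length(unique(worst$patient)),
               g1 = length(unique(worst$patient[worst$col == "g1"])),
               g2 = length(unique(worst$patient[worst$col == "g2"])),
               g3plus = length(unique(worst$patient[worst$col == "g3plus"])))
  tab <- rbind(Any = any_row, rows)
  out <- data.frame(term = c("Any", terms),
                    n_any = tab[, "any"],
                    pct_any = round_half_up(100 * tab[, "any"] / n_patients, 1),
                    n_g1 = tab[, "g1"],
                    pct_g1 = round_half_up(100 * tab[, "g1"] / n_patients, 1),
                    n_g2 = tab[, "g2"],
                    pct_g2 = round_half_up(100 * tab[, "g2"] / n_patients, 1),
                    n_g3plus = tab[, "g3plus"],
                    pct_g3plus = round_half_up(100 * tab[, "g3plus"] / n_patients, 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' 3+3 dose-escalation bookkeeping
#'
#' Standard modified 3+3 transitions with a single-patient accelerated
#' start at the lowest dose: a cleared accelerated patient (0/1 DLT)
#' escalates; 0/3 DLT escalates; 1/3 expands the level to six; two or
#' more DLTs at a level exceed the maximum tolerated dose and the MTD is
#' the previous level; clearing the top level declares it the MTD.
#'
#' @param outcomes data.frame with one row per dose level, ascending
#'   dose: `dose_mg`, `n_enrolled`, `n_dlt`. Levels not yet opened carry
#'   `n_enrolled = 0`.
#' @param accelerated is the lowest level run as a single-patient
#'   accelerated titration?
#' @return list with `action` (one of `enroll-1 accelerated`,
#'   `expand-to-3`, `expand-to-6`, `escalate`, `de-escalate/stop`,
#'   `declare-MTD`), `level` (dose acted on) and `mtd` (mg, or `NA` while
#'   undetermined).
#' @export
escalation_state <- function(outcomes, accelerated = TRUE) {
  req <- c("dose_mg", "n_enrolled", "n_dlt")
  miss <- setdiff(req, names(outcomes))
  if (length(miss)) stop("outcomes missing column(s): ", paste(miss, collapse = ", "))
  if (any(outcomes$n_dlt > outcomes$n_enrolled))
    stop("DLT outcomes reported for unenrolled patients")
  o <- outcomes[order(outcomes$dose_mg), , drop = FALSE]
  for (i in seq_len(nrow(o))) {
    n <- o$n_enrolled[i]; d <- o$n_dlt[i]; dose <- o$dose_mg[i]
    top <- i == nrow(o)
    prev_dose <- if (i > 1) o$dose_mg[i - 1] else NA_real_
    if (n == 0) {
      action <- if (i == 1) {
        if (accelerated) "enroll-1 accelerated" else "expand-to-3"
      } else "escalate"                      # previous level cleared; open this one
      return(list(action = action, level = dose, mtd = NA_real_))
    }
    if (i == 1 && accelerated && n == 1) {
      if (d == 0) next                       # accelerated patient cleared
      return(list(action = "expand-to-3", level = dose, mtd = NA_real_))
    }
    if (n < 3) return(list(action = "expand-to-3", level = dose, mtd = NA_real_))
    if (n < 6) {
      if (d == 0) {
        if (top) return(list(action = "declare-MTD", level = dose, mtd = dose))
        next                                 # escalate past a clean triplet
      }
      if (d == 1) return(list(action = "expand-to-6", level = dose, mtd = NA_real_))
      return(list(action = "de-escalate/stop", level = dose, mtd = prev_dose))
    }
    if (d <= 1) {
      if (top) return(list(action = "declare-MTD", level = dose, mtd = dose))
      next
    }
    return(list(action = "de-escalate/stop", level = dose, mtd = prev_dose))
  }
  top_dose <- o$dose_mg[nrow(o)]
  list(action = "declare-MTD", level = top_dose, mtd = top_dose)
}
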