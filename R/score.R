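#' Tumor-vs-normal differential expression filter
#'
#' Per-gene two-sided Wilcoxon rank-sum test of tumor against normal
#' samples with Benjamini-Hochberg adjustment across genes; genes with
#' adjusted p below `alpha_fdr` are selected. A Welch t-test mode is
#' available for roughly Gaussian expression scales.
#'
#' @param cohort a [survival_cohort()] with expression and tissue labels
#'   (>= 3 tumor and >= 3 normal samples).
#' @param alpha_fdr BH-adjusted significance cutoff.
#' @param genes genes to test; default every expression row.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return list with `selected` (gene ids) and `table` (gene, p, padj).
#' @export
de_filter <- function(cohort, alpha_fdr = 0.05, genes = NULL,
                      test = c("wilcoxon", "t")) {
  stopifnot(inherits(cohort, "survival_cohort"))
  test <- match.arg(test)
  if (is.null(cohort$expression) || is.null(cohort$tissue))
    stop("cohort lacks expression or tissue labels")
  tum <- names(cohort$tissue)[cohort$tissue == "tumor"]
  nor <- names(cohort$tissue)[cohort$tissue == "normal"]
  if (length(tum) < 3 || length(nor) < 3)
    stop("need >= 3 tumor and >= 3 normal samples")
  if (is.null(genes)) genes <- rownames(cohort$expression)
  if (!all(genes %in% rownames(cohort$expression)))
    stop("unknown gene(s): ",
         paste(utils::head(setdiff(genes, rownames(cohort$expression)), 5), collapse = ", "))
  p <- vapply(genes, function(g) {
    a <- cohort$expression[g, tum]
    b <- cohort$expression[g, nor]
    if (stats::sd(c(a, b)) == 0) return(1)
    if (test == "wilcoxon")
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    else stats::t.test(a, b)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = genes, p = unname(p), padj = unname(padj),
                    selected = unname(padj < alpha_fdr), stringsAsFactors = FALSE)
  list(selected = tab$gene[tab$selected], table = tab)
}

#' Univariate Cox regression for one gene
#'
#' Fits a single-covariate Cox proportional-hazards model of survival on
#' the gene's expression, Breslow tie handling by default, and returns the
#' log-hazard coefficient, hazard ratio and Wald p-value. A constant
#' covariate carries no information and returns `beta = 0`; apparent
#' monotone separation (very large `|beta|` or non-convergence) is flagged
#' so callers can exclude the gene.
#'
#' @param cohort a [survival_cohort()]; at least 5 events are required,
#'   and fewer than 10 subjects draws a small-cohort warning.
#' @param gene gene id present in the expression matrix.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `beta`, `hr`, `se`, `p`, `converged`, `flag`.
#' @export
cox_univariate <- function(cohort, gene, ties = c("breslow", "efron")) {
  stopifnot(inherits(cohort, "survival_cohort"))
  ties <- match.arg(ties)
  if (sum(cohort$event) < 5) stop("need >= 5 events")
  if (length(cohort$subject_id) < 10)
    warning("fewer than 10 subjects; coefficient is unstable")
  if (!gene %in% rownames(cohort$expression)) stop("unknown gene: ", gene)
  x <- cohort$expression[gene, cohort$subject_id]
  if (stats::sd(x) == 0)
    return(list(beta = 0, hr = 1, se = NA_real_, p = NA_real_,
                converged = TRUE, flag = "constant covariate"))
  fit <- tryCatch(
    survival::coxph(survival::Surv(cohort$time, cohort$event) ~ x,
                    ties = ties),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(cohort$time, cohort$event) ~ x, ties = ties))
      attr(f, "warned") <- conditionMessage(w)
      f
    },
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit)))
    return(list(beta = NA_real_, hr = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE, flag = "non-convergence"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  flag <- NULL
  if (!is.null(attr(fit, "warned")) || abs(beta) > 10)
    flag <- "possible complete separation"
  list(beta = beta, hr = exp(beta), se = se,
       p = unname(summary(fit)$coefficients[, "Pr(>|z|)"]),
       converged = TRUE, flag = flag)
}

#' Build the Cox-weighted score model (DNBscore)
#'
#' From the panel genes, keeps those that are differentially expressed
#' between tumor and normal tissue ([de_filter()], BH-adjusted
#' `p < alpha_fdr`) and prognostic in univariate Cox regression
#' (`p < alpha_cox`), and records each retained gene's log-hazard
#' coefficient. The resulting model maps an expression profile to the
#' scalar `score = sum_g beta_g * x_g` (see [score_subjects()]).
#' Expression enters the score on the scale the coefficients were fitted
#' on; no rescaling is applied.
#'
#' @param cohort a [survival_cohort()] with expression, tissue labels and
#'   survival follow-up.
#' @param panel candidate gene ids (non-empty); genes absent from the
#'   cohort's expression are dropped with a warning.
#' @param alpha_fdr DE filter cutoff (BH-adjusted).
#' @param alpha_cox univariate Cox Wald-p cutoff.
#' @param ties Cox tie handling.
#' @return Object of class `score_model`: `genes`, `betas` and a
#'   `provenance` data.frame recording both filters for every panel gene.
#' @export
build_score_model <- function(cohort, panel, alpha_fdr = 0.05, alpha_cox = 0.05,
                              ties = "breslow") {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (length(panel) == 0) stop("empty panel")
  known <- intersect(panel, rownames(cohort$expression))
  if (length(known) < length(panel))
    warning("panel gene(s) absent from cohort expression: ",
            paste(setdiff(panel, known), collapse = ", "))
  if (length(known) == 0) stop("no panel gene measured in the cohort")
  de <- de_filter(cohort, alpha_fdr = alpha_fdr, genes = known)
  cox <- lapply(known, function(g) cox_univariate(cohort, g, ties = ties))
  prov <- data.frame(
    gene = known,
    de_p = de$table$p, de_padj = de$table$padj, de_pass = de$table$selected,
    cox_beta = vapply(cox, function(z) z$beta, numeric(1)),
    cox_p = vapply(cox, function(z) z$p, numeric(1)),
    cox_flag = vapply(cox, function(z) if (is.null(z$flag)) "" else z$flag,
                      character(1)),
    stringsAsFactors = FALSE)
  prov$cox_pass <- !is.na(prov$cox_p) & prov$cox_p < alpha_cox &
    prov$cox_flag == ""
  prov$retained <- prov$de_pass & prov$cox_pass
  if (!any(prov$retained))
    stop("no gene passes both the DE and the Cox filter")
  genes <- prov$gene[prov$retained]
  structure(list(genes = genes,
                 betas = stats::setNames(prov$cox_beta[prov$retained], genes),
                 provenance = prov,
                 thresholds = c(alpha_fdr = alpha_fdr, alpha_cox = alpha_cox)),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("score_model:", length(x$genes), "gene(s) of",
      nrow(x$provenance), "candidates retained",
      sprintf("(DE padj < %g, Cox p < %g)\n",
              x$thresholds["alpha_fdr"], x$thresholds["alpha_cox"]))
  print(data.frame(gene = x$genes, beta = unname(x$betas)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.score_model <- function(object, ...) object$betas

#' Score subjects with a fitted model
#'
#' `score_i = sum_g beta_g x_gi`, linear in expression and invariant to
#' gene order. A missing model gene is an error, never a silent zero.
#'
#' @param model a `score_model`.
#' @param expr gene x subject expression matrix containing every model
#'   gene.
#' @return named numeric vector of scores.
#' @export
score_subjects <- function(model, expr) {
  stopifnot(inherits(model, "score_model"))
  miss <- setdiff(model$genes, rownames(expr))
  if (length(miss))
    stop("expression lacks model gene(s): ", paste(miss, collapse = ", "))
  drop(crossprod(expr[model$genes, , drop = FALSE], model$betas[model$genes]))
}

#' @export
predict.score_model <- function(object, newdata, ...) score_subjects(object, newdata)

#' Write / read a score model (CSV coefficients + JSON provenance)
#'
#' `basename.csv` holds `gene, beta` at full precision; `basename.json`
#' the provenance table and thresholds. The round trip is bit-identical
#' for the coefficients.
#'
#' @param model a `score_model`.
#' @param basename path prefix (without extension).
#' @return `write_score_model`: the paths written, invisibly;
#'   `read_score_model`: the restored `score_model`.
#' @export
write_score_model <- function(model, basename) {
  stopifnot(inherits(model, "score_model"))
  csv <- paste0(basename, ".csv")
  json <- paste0(basename, ".json")
  df <- data.frame(gene = model$genes,
                   beta = sprintf("%.17g", unname(model$betas)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(provenance = model$provenance,
                            thresholds = as.list(model$thresholds)),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' @rdname write_score_model
#' @export
read_score_model <- function(basename) {
  csv <- paste0(basename, ".csv")
  json <- paste0(basename, ".json")
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  meta <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
          else list(provenance = NULL, thresholds = NULL)
  structure(list(genes = df$gene,
                 betas = stats::setNames(as.numeric(df$beta), df$gene),
                 provenance = meta$provenance,
                 thresholds = unlist(meta$thresholds)),
            class = "score_model")
}

#' Median-split stratification
#'
#' Scores strictly above the cohort median are `high`; scores at or below
#' it are `low` (the printed definition of the high-score group is
#' "above the median", so a subject exactly at the median is low). An
#' all-identical score vector cannot be stratified and errors.
#'
#' @param scores numeric scores (>= 2 subjects).
#' @return factor with levels `low`, `high`, named like `scores`.
#' @export
median_stratify <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 subjects")
  if (stats::sd(scores) == 0) stop("all scores identical; no stratification possible")
  med <- stats::median(scores)
  stats::setNames(factor(ifelse(scores > med, "high", "low"),
                         levels = c("low", "high")), names(scores))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard two-group
#' log-rank chi-square.
#'
#' @param time,event follow-up and 1/0 event flag.
#' @param group two-level grouping; each group must contain at least one
#'   event.
#' @return list with `km` (data.frame: group, time, n_risk, n_event,
#'   survival), `chisq`, `p` and the underlying `survfit` object (for
#'   plotting).
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("need exactly two groups")
  if (any(tapply(event, group, sum) < 1)) stop("each group needs >= 1 event")
  if (any(tapply(event, group, length) < 1)) stop("empty group")
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  strata <- rep(names(sf$strata), sf$strata)
  km <- data.frame(group = sub("^group=", "", strata),
                   time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, survival = sf$surv,
                   stringsAsFactors = FALSE)
  list(km = km, chisq = unname(sd_$chisq), p = p, fit = sf)
}

#' Multivariate Cox model for score group and clinical covariates
#'
#' Joint Breslow Cox fit of survival on the score group plus covariates
#' (age and stage by default), returning a forest-plot-ready table of
#' hazard ratios with 95% confidence intervals and Wald p-values.
#' Linearly dependent covariate columns are rejected.
#'
#' @param cohort a [survival_cohort()] with complete covariates.
#' @param score_group factor per subject (e.g. from [median_stratify()]).
#' @param covariates covariate column names to adjust for.
#' @param ties Cox tie handling.
#' @return data.frame: term, hr, ci_low, ci_high, p.
#' @export
cox_multivariate <- function(cohort, score_group, covariates = c("age", "stage"),
                             ties = "breslow") {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (length(score_group) != length(cohort$subject_id))
    stop("score_group must cover every subject")
  miss <- setdiff(covariates, names(cohort$covariates))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  df <- data.frame(time = cohort$time, event = cohort$event,
                   score_group = as.factor(score_group),
                   cohort$covariates[, covariates, drop = FALSE])
  if (anyNA(df)) stop("covariates must be complete")
  mm <- stats::model.matrix(~ score_group + ., data = df[, -(1:2), drop = FALSE])
  if (qr(mm)$rank < ncol(mm))
    stop("collinear covariates: design matrix is rank deficient")
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df, ties = ties)
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             hr = unname(s$coefficients[, "exp(coef)"]),
             ci_low = unname(s$conf.int[, "lower .95"]),
             ci_high = unname(s$conf.int[, "upper .95"]),
             p = unname(s$coefficients[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

#' ROC curve and response-associated score cutoff
#'
#' Sweeps the score as a classifier of objective response, reports the
#' area under the ROC curve, and picks the cutoff maximizing Youden's J
#' (sensitivity + specificity - 1); among tied thresholds the lowest
#' cutoff wins. Subjects are then labelled `low`/`high` against the
#' cutoff for response tabulation.
#'
#' @param scores numeric score per subject.
#' @param response logical or two-level label; `TRUE`/`"PR"`/`"responder"`
#'   counts as a response.
#' @return list with `auc`, `cutoff`, `youden`, `groups` (factor
#'   low/high) and the `pROC::roc` object.
#' @export
response_cutoff <- function(scores, response) {
  resp <- if (is.logical(response)) response
          else response %in% c("PR", "CR", "responder", "yes", "1", "TRUE")
  if (length(unique(resp)) < 2) stop("both response classes must be present")
  roc <- pROC::roc(response = resp, predictor = scores, quiet = TRUE,
                   direction = "auto", levels = c(FALSE, TRUE))
  co <- pROC::coords(roc, x = "all", ret = c("threshold", "sensitivity",
                                             "specificity"), transpose = FALSE)
  co$youden <- co$sensitivity + co$specificity - 1
  co <- co[is.finite(co$threshold), , drop = FALSE]
  best <- co[co$youden >= max(co$youden) - 1e-12, , drop = FALSE]
  cutoff <- min(best$threshold)
  groups <- stats::setNames(factor(ifelse(scores > cutoff, "high", "low"),
                                   levels = c("low", "high")), names(scores))
  list(auc = as.numeric(pROC::auc(roc)), cutoff = cutoff,
       youden = max(co$youden), groups = groups, roc = roc)
}

#' Tabulate objective response by score group
#'
#' Counts and response (PR/CR) rates per group and overall, on the
#' percentage scale rounded half-up to one decimal, matching trial-report
#' formatting.
#'
#' @param group factor of score groups (`low`/`high` or similar).
#' @param response per-subject labels; `PR`/`CR` count as objective
#'   response.
#' @return data.frame: group, n, n_response, pr_rate_pct.
#' @export
response_tabulation <- function(group, response) {
  if (length(group) != length(response)) stop("length mismatch")
  group <- as.factor(group)
  resp <- response %in% c("PR", "CR")
  rows <- lapply(levels(group), function(g) {
    n <- sum(group == g)
    r <- sum(resp[group == g])
    data.frame(group = g, n = n, n_response = r,
               pr_rate_pct = round_half_up(100 * r / n, 1))
  })
  rows <- c(rows, list(data.frame(group = "overall", n = length(resp),
                                  n_response = sum(resp),
                                  pr_rate_pct = round_half_up(100 * mean(resp), 1))))
  do.call(rbind, rows)
}

#' Spearman correlation of a score with cell-infiltration fractions
#'
#' Per cell type, two-sided Spearman correlation between the subject
#' scores and the infiltration fraction, with BH adjustment across cell
#' types. Subjects are intersected between the two inputs (>= 5 required);
#' a mismatch beyond the intersection warns.
#'
#' @param scores named numeric scores per subject.
#' @param fractions cell-type x subject matrix (e.g. [read_fractions()]).
#' @return data.frame: cell_type, rho, p, padj.
#' @export
fraction_correlation <- function(scores, fractions) {
  common <- intersect(names(scores), colnames(fractions))
  if (length(common) < 5) stop("insufficient subject overlap (< 5)")
  if (length(common) < length(scores) || length(common) < ncol(fractions))
    warning("subject mismatch; using the intersection of ",
            length(common), " subjects")
  res <- lapply(rownames(fractions), function(ct) {
    ct_test <- suppressWarnings(
      stats::cor.test(scores[common], fractions[ct, common],
                      method = "spearman", exact = FALSE))
    data.frame(cell_type = ct, rho = unname(ct_test$estimate),
               p = ct_test$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}
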