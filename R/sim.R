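#' Simulate a longitudinal NPX cohort with a planted DNB cluster
#'
#' Generates serial plasma-proteomics measurements with the structure a
#' dynamic-network-biomarker analysis assumes: at baseline (`D0`) all
#' proteins are independent Gaussians on the NPX (log2-like) scale; at the
#' post-baseline time points a planted cluster of `n_planted` proteins has
#' its cross-patient standard deviation amplified by `sd_amplification`
#' and acquires exchangeable pairwise correlation `rho_in` through a shared
#' latent factor (`x = sqrt(rho) z_common + sqrt(1 - rho) z_own`), while
#' background proteins keep their baseline spread and are correlated with
#' the planted cluster at `rho_out` (background-background correlation is
#' then `rho_out^2 / rho_in`, effectively zero at the defaults). Poor
#' responders carry a baseline mean shift of `effect_shift` NPX units on
#' the planted proteins, giving the group-separable `D0` profiles the
#' supervised selection step looks for.
#'
#' `sd_amplification` is the ratio of post-baseline to baseline standard
#' deviation of the planted proteins; when `effect_shift != 0` the
#' realized baseline SD includes the responder-mixture variance and the
#' amplification is applied to that realized SD, so the population SD
#' ratio equals `sd_amplification` exactly under all settings.
#'
#' Defaults mirror the study conditions used throughout the package's
#' validation: 40 patients, 120 proteins, a 12-protein planted cluster,
#' three-fold variance amplification, `rho_in = 0.7`, `rho_out = 0.1`, a
#' GoR fraction of 5/9 and a 1 NPX-unit baseline shift. A planted cluster
#' is only recoverable by the two-fold SD filter when
#' `sd_amplification > 2` (documented, not enforced).
#'
#' @param n_patients,n_proteins,n_planted cohort dimensions;
#'   `n_planted < n_proteins`.
#' @param timepoints ordered time-point labels; the first is the baseline
#'   reference.
#' @param sd_amplification positive ratio of post-baseline to baseline SD
#'   for planted proteins.
#' @param rho_in,rho_out intra-cluster and cluster-to-background
#'   correlation at post-baseline time points; `0 <= rho_out <= rho_in < 1`
#'   and `rho_out > 0` requires `rho_in > 0`.
#' @param frac_gor fraction of patients labelled `GoR`.
#' @param effect_shift baseline mean shift (NPX units) of planted proteins
#'   in `PoR` patients.
#' @param dropout if `TRUE`, reproduce the uneven sampling of a small
#'   dose-escalation trial: the fourth time point becomes `PD`, kept only
#'   for a minority of patients, and other visits are thinned, so
#'   [assign_lt()] has real work to do. Default off.
#' @param seed integer seed; equal seeds give bit-identical output.
#' @return A list with `npx` (an [npx_matrix()]) and `truth`
#'   (`planted` protein ids, `groups` per patient).
#' @export
sim_longitudinal_npx <- function(n_patients = 40, n_proteins = 120, n_planted = 12,
                                 timepoints = c("D0", "D5", "DT", "LT"),
                                 sd_amplification = 3, rho_in = 0.7, rho_out = 0.1,
                                 frac_gor = 5 / 9, effect_shift = 1,
                                 dropout = FALSE, seed = NULL) {
  if (n_patients < 2 || n_proteins < 2 || n_planted < 1)
    stop("counts must be positive (>= 2 patients and proteins)")
  if (n_planted >= n_proteins) stop("n_planted must be < n_proteins")
  if (rho_in < 0 || rho_in >= 1 || rho_out < 0 || rho_out > rho_in)
    stop("need 0 <= rho_out <= rho_in < 1")
  if (rho_out > 0 && rho_in == 0) stop("rho_out > 0 requires rho_in > 0")
  if (sd_amplification <= 0) stop("sd_amplification must be positive")
  l_bg <- if (rho_in > 0) rho_out / sqrt(rho_in) else 0
  if (l_bg > 1) stop("rho_out/sqrt(rho_in) > 1: correlation model not positive semi-definite")
  if (dropout) timepoints <- c(timepoints[-length(timepoints)], "PD")
  if (!is.null(seed)) set.seed(seed)

  proteins <- sprintf("P%03d", seq_len(n_proteins))
  patients <- sprintf("PT%02d", seq_len(n_patients))
  planted <- proteins[seq_len(n_planted)]
  n_gor <- round(frac_gor * n_patients)
  groups <- rep(c("GoR", "PoR"), c(n_gor, n_patients - n_gor))
  p_por <- 1 - n_gor / n_patients

  mu <- stats::rnorm(n_proteins, mean = 8, sd = 2)      # per-protein NPX level
  sd0_planted <- sqrt(1 + p_por * (1 - p_por) * effect_shift^2)
  is_planted <- seq_len(n_proteins) <= n_planted

  tp_mats <- vector("list", length(timepoints))
  names(tp_mats) <- timepoints
  for (k in seq_along(timepoints)) {
    tp <- timepoints[k]
    if (k == 1L) {                                      # baseline: iid + PoR shift
      v <- mu + matrix(stats::rnorm(n_proteins * n_patients), n_proteins)
      v[is_planted, groups == "PoR"] <- v[is_planted, groups == "PoR"] + effect_shift
    } else {
      z_common <- stats::rnorm(n_patients)              # shared latent factor at this visit
      eps <- matrix(stats::rnorm(n_proteins * n_patients), n_proteins)
      v <- matrix(0, n_proteins, n_patients)
      v[is_planted, ] <- sd_amplification * sd0_planted *
        (sqrt(rho_in) * rep(z_common, each = n_planted) +
           sqrt(1 - rho_in) * eps[is_planted, , drop = FALSE])
      v[!is_planted, ] <- l_bg * rep(z_common, each = n_proteins - n_planted) +
        sqrt(1 - l_bg^2) * eps[!is_planted, , drop = FALSE]
      v <- mu + v
    }
    dimnames(v) <- list(proteins, paste(patients, tp, sep = "_"))
    tp_mats[[k]] <- v
  }
  values <- do.call(cbind, tp_mats)
  sm <- data.frame(
    sample_id = colnames(values),
    patient_id = rep(patients, times = length(timepoints)),
    timepoint = rep(timepoints, each = n_patients),
    order = rep(seq_along(timepoints), each = n_patients),
    stringsAsFactors = FALSE)

  if (dropout) {
    # retention per visit mirrors a 9/9/8/4-of-11 sampling design
    keep_prob <- c(9, 9, 8, 4) / 11
    keep_prob <- keep_prob[seq_along(timepoints)]
    keep <- stats::runif(nrow(sm)) <= keep_prob[sm$order]
    for (pt in patients)                                # every patient keeps >= 1 sample
      if (!any(keep[sm$patient_id == pt]))
        keep[which(sm$patient_id == pt)[1L]] <- TRUE
    sm <- sm[keep, , drop = FALSE]
    values <- values[, sm$sample_id, drop = FALSE]
  }

  pm <- data.frame(patient_id = patients, group = groups, stringsAsFactors = FALSE)
  list(npx = npx_matrix(values, sm, pm),
       truth = list(planted = planted,
                    groups = stats::setNames(groups, patients)))
}

#' Simulate a tumor/normal expression cohort with proportional-hazards survival
#'
#' Expression is Gaussian per gene; a designated subset is shifted by
#' `de_shift` in tumor relative to normal samples (the differential-
#' expression truth). Event times are exponential with hazard
#' `baseline_hazard * exp(sum(beta_g x_g))` so the cohort satisfies
#' proportional hazards by construction; censoring is independent
#' exponential with rate `censor_rate` (`0` disables censoring). Age and a
#' 1-4 ordinal stage are generated independently of expression, mimicking
#' the covariates of a public gastric-cancer survival cohort.
#'
#' @param n_subjects tumor subjects with survival follow-up.
#' @param n_genes genes measured.
#' @param true_betas per-gene log-hazard coefficients; default `0.7` on
#'   the first three genes, zero elsewhere.
#' @param baseline_hazard events per unit time for a subject at the
#'   expression origin; must be positive.
#' @param censor_rate independent censoring rate (`>= 0`).
#' @param n_normal normal-tissue samples (no survival rows).
#' @param de_genes gene ids carrying the tumor-vs-normal shift; default
#'   the first five genes.
#' @param de_shift mean tumor-vs-normal expression shift on `de_genes`.
#' @param seed integer seed.
#' @return A list with `cohort` (a [survival_cohort()]) and `truth`
#'   (`betas`, `de_genes`).
#' @export
sim_survival_cohort <- function(n_subjects = 400, n_genes = 20, true_betas = NULL,
                                baseline_hazard = 0.1, censor_rate = 0.05,
                                n_normal = 50, de_genes = NULL, de_shift = 2,
                                seed = NULL) {
  if (n_subjects < 2 || n_genes < 1 || n_normal < 0) stop("non-positive counts")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0 (all-zero hazard)")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(true_betas))
    true_betas <- stats::setNames(c(rep(0.7, min(3, n_genes)),
                                    rep(0, max(0, n_genes - 3))), genes)
  if (is.null(names(true_betas))) names(true_betas) <- genes
  if (is.null(de_genes)) de_genes <- genes[seq_len(min(5, n_genes))]
  if (!is.null(seed)) set.seed(seed)

  subjects <- sprintf("S%03d", seq_len(n_subjects))
  normals <- if (n_normal > 0) sprintf("N%03d", seq_len(n_normal)) else character()
  expr <- matrix(stats::rnorm(n_genes * (n_subjects + n_normal)), n_genes,
                 dimnames = list(genes, c(subjects, normals)))
  expr[de_genes, subjects] <- expr[de_genes, subjects] + de_shift

  lp <- drop(crossprod(expr[names(true_betas), subjects, drop = FALSE], true_betas))
  t_event <- stats::rexp(n_subjects, rate = baseline_hazard * exp(lp))
  t_cens <- if (censor_rate > 0) stats::rexp(n_subjects, rate = censor_rate) else Inf
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  age <- pmin(pmax(stats::rnorm(n_subjects, 63, 10), 35), 80)
  stage <- sample(1:4, n_subjects, replace = TRUE)
  cohort <- survival_cohort(
    subject_id = subjects, time = time, event = event,
    covariates = data.frame(age = age, stage = stage),
    expression = expr,
    tissue = stats::setNames(rep(c("tumor", "normal"), c(n_subjects, n_normal)),
                             c(subjects, normals)),
    time_unit = "months")
  list(cohort = cohort, truth = list(betas = true_betas, de_genes = de_genes))
}

#' Simulate a batch-shifted validation cohort linked to a score model
#'
#' Emulates an external expression cohort on which a fitted [score
#' model][build_score_model()] is evaluated: expression of the model genes
#' is drawn as in the survival generator, then shifted by `batch_shift` on
#' every gene (the batch effect [adjust_batches()] removes). The
#' probability of objective response (`PR`) follows a logistic link that
#' decreases with the true score: `plogis(qlogis(base_pr) -
#' response_link_strength * z)` with `z` the standardized true score, so
#' `response_link_strength` is the logit slope per score SD and `0` makes
#' the labels independent of the score. Non-responders split evenly
#' between `SD` and `PD`.
#'
#' @param model a `score_model` (non-empty).
#' @param n_subjects validation subjects.
#' @param batch_shift per-gene additive batch offset.
#' @param response_link_strength logit slope (per score SD) linking low
#'   score to response.
#' @param base_pr marginal response probability at the median score.
#' @param seed integer seed.
#' @return A list with `expression` (gene x subject), `response`
#'   (`PR`/`SD`/`PD`), `batch` labels and `truth` (`score`, `p_response`).
#' @export
sim_validation_cohort <- function(model, n_subjects = 200, batch_shift = 2,
                                  response_link_strength = 5, base_pr = 0.238,
                                  seed = NULL) {
  if (!inherits(model, "score_model") || length(model$genes) == 0)
    stop("`model` must be a non-empty score_model")
  if (!is.null(seed)) set.seed(seed)
  genes <- model$genes
  subjects <- sprintf("V%03d", seq_len(n_subjects))
  expr <- matrix(stats::rnorm(length(genes) * n_subjects), length(genes),
                 dimnames = list(genes, subjects))
  score <- drop(crossprod(expr, model$betas[genes]))
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score) else score * 0
  p <- stats::plogis(stats::qlogis(base_pr) - response_link_strength * z)
  resp <- ifelse(stats::runif(n_subjects) < p, "PR",
                 sample(c("SD", "PD"), n_subjects, replace = TRUE))
  expr <- expr + batch_shift
  list(expression = expr,
       response = stats::setNames(resp, subjects),
       batch = stats::setNames(rep("validation", n_subjects), subjects),
       truth = list(score = stats::setNames(score, subjects),
                    p_response = stats::setNames(p, subjects)))
}
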