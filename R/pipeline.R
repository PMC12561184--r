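#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default; [read_run_config()]
#' overlays a YAML file on top of this and rejects unknown keys. Paths are
#' resolved relative to the working directory.
#'
#' @return named list of settings.
#' @export
default_run_config <- function() {
  list(
    out_dir = "dnbscore_out",
    seed = 1,
    # synthetic cohort
    n_patients = 40, n_proteins = 120, n_planted = 12,
    sd_amplification = 3, rho_in = 0.7, rho_out = 0.1,
    frac_gor = 5 / 9, effect_shift = 1,
    n_subjects = 400, n_genes = 20, baseline_hazard = 0.1,
    censor_rate = 0.05, n_normal = 50, de_shift = 2,
    n_validation = 200, batch_shift = 2, response_link_strength = 5,
    # selection / detection
    vip_threshold = 1, n_components = 2,
    fold = 2, sd_mode = "conjunctive", c_min = 2, c_max = 8,
    m_fuzz = 1.25, sil_min = 0.5, n_perm = 1000, eps = 1e-6,
    # scoring
    alpha = 0.05, alpha_fdr = 0.05, alpha_cox = 0.05, ties = "breslow",
    roc_target = "response",
    # inputs (defaults point at the files `simulate` writes)
    npx_file = NULL, survival_file = NULL, expression_file = NULL,
    tissue_file = NULL, validation_expression_file = NULL,
    validation_response_file = NULL, lesions_file = NULL, teae_file = NULL)
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file with a subset of the keys of
#'   [default_run_config()]; unknown keys are a validation error.
#' @return full configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop(errorCondition(paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")),
                        class = c("dnbscore_validation_error", "error", "condition")))
  base[names(cfg)] <- cfg
  base
}

.cfg_path <- function(config, key, default) {
  p <- config[[key]]
  if (is.null(p)) file.path(config$out_dir, default) else p
}

.file_md5 <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the analysis pipeline
#'
#' One entry point wiring every stage per a single configuration:
#' `simulate` writes a full synthetic input set (longitudinal NPX,
#' tumor/normal survival cohort, batch-shifted validation cohort, and the
#' reconstructed trial lesion/TEAE tables shipped with the package);
#' `plsda` runs the two response-group contrasts; `dnb` the variance-burst
#' detection and the panel intersection; `score` the DE + Cox score model
#' with survival stratification; `validate` the batch adjustment, scoring
#' and response tabulation of the validation cohort; `clinical` the
#' RECIST/TEAE/escalation worked tables; `all` chains everything. Outputs
#' land only under `config$out_dir`, inputs are never mutated, and a JSON
#' manifest records settings, input checksums and the filter-count chain.
#'
#' @param subcommand one of `simulate`, `plsda`, `dnb`, `score`,
#'   `validate`, `clinical`, `all`.
#' @param config list from [default_run_config()] / [read_run_config()].
#' @param quiet suppress progress messages.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "plsda", "dnb",
                                        "score", "validate", "clinical"),
                         config = default_run_config(), quiet = FALSE) {
  subcommand <- match.arg(subcommand)
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("dnbscore")),
                   subcommand = subcommand, config = config,
                   inputs = list(), counts = list())
  steps <- if (subcommand == "all")
    c("simulate", "plsda", "dnb", "score", "validate", "clinical")
  else subcommand

  if ("simulate" %in% steps) {
    say("[simulate] generating synthetic cohorts (seed ", config$seed, ")")
    lon <- sim_longitudinal_npx(
      n_patients = config$n_patients, n_proteins = config$n_proteins,
      n_planted = config$n_planted, sd_amplification = config$sd_amplification,
      rho_in = config$rho_in, rho_out = config$rho_out,
      frac_gor = config$frac_gor, effect_shift = config$effect_shift,
      seed = config$seed)
    write_npx_long(lon$npx, file.path(config$out_dir, "npx_long.csv"))
    utils::write.csv(data.frame(protein_id = lon$truth$planted),
                     file.path(config$out_dir, "truth_planted.csv"),
                     row.names = FALSE)
    sur <- sim_survival_cohort(
      n_subjects = config$n_subjects, n_genes = config$n_genes,
      baseline_hazard = config$baseline_hazard,
      censor_rate = config$censor_rate, n_normal = config$n_normal,
      de_shift = config$de_shift, seed = config$seed + 1L)
    co <- sur$cohort
    utils::write.csv(data.frame(subject_id = co$subject_id, time = co$time,
                                event = co$event, co$covariates),
                     file.path(config$out_dir, "survival.csv"), row.names = FALSE)
    utils::write.csv(data.frame(gene = rownames(co$expression), co$expression,
                                check.names = FALSE),
                     file.path(config$out_dir, "expression.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample = names(co$tissue), tissue = co$tissue),
                     file.path(config$out_dir, "tissue.csv"), row.names = FALSE)
    for (f in c("lesions_reconstructed.csv", "teae_listing_reconstructed.csv"))
      file.copy(system.file("extdata", f, package = "dnbscore"),
                file.path(config$out_dir, f), overwrite = TRUE)
    manifest$counts$proteins_in <- config$n_proteins
  }

  npx <- NULL
  get_npx <- function() {
    if (is.null(npx)) {
      f <- .cfg_path(config, "npx_file", "npx_long.csv")
      manifest$inputs$npx <<- .file_md5(f)
      npx <<- assign_lt(read_npx_long(f))
    }
    npx
  }

  if ("plsda" %in% steps) {
    say("[plsda] GoR-vs-PoR contrasts (D0 and all samples), VIP >= ",
        config$vip_threshold)
    m <- get_npx()
    ctr <- run_group_contrasts(m, ncomp = config$n_components,
                               threshold = config$vip_threshold)
    sel <- rbind(cbind(ctr$d0$selection, contrast = "D0"),
                 cbind(ctr$all$selection, contrast = "all"))
    utils::write.csv(sel, file.path(config$out_dir, "plsda_selection.csv"),
                     row.names = FALSE)
    manifest$counts$plsda_d0 <- nrow(ctr$d0$selection)
    manifest$counts$plsda_all <- nrow(ctr$all$selection)
  }

  if ("dnb" %in% steps) {
    say("[dnb] SD filter (", config$fold, "x, ", config$sd_mode,
        "), fuzzy clustering, criticality index")
    m <- get_npx()
    det <- dnb_detect(m, fold = config$fold, sd_mode = config$sd_mode,
                      c_range = config$c_min:config$c_max,
                      m_fuzz = config$m_fuzz, sil_min = config$sil_min,
                      n_perm = config$n_perm, alpha = config$alpha,
                      eps = config$eps, seed = config$seed)
    idx <- do.call(rbind, lapply(det$reports, function(r)
      data.frame(cluster_id = r$cluster_id, n_members = length(r$members),
                 sd_avg = r$sd_avg, ppc_in = r$ppc_in, ppc_out = r$ppc_out,
                 ci = r$ci, p_ppci = r$p_ppci, p_ppco = r$p_ppco,
                 passes_all = all(r$passes_criteria))))
    utils::write.csv(idx, file.path(config$out_dir, "dnb_clusters.csv"),
                     row.names = FALSE)
    sel_file <- file.path(config$out_dir, "plsda_selection.csv")
    panel_prot <- det$members
    if (file.exists(sel_file)) {
      sel <- utils::read.csv(sel_file, stringsAsFactors = FALSE)
      panel <- build_panel(det$members, unique(sel$protein_id),
                           provenance = paste0("cluster=", det$winner$cluster_id))
      panel_prot <- panel$proteins
    } else {
      say("[dnb] no PLS-DA selection found; panel = winning cluster members")
    }
    utils::write.csv(data.frame(protein_id = panel_prot),
                     file.path(config$out_dir, "dnb_panel.csv"), row.names = FALSE)
    manifest$counts$sd_passed <- length(det$filter$candidates)
    manifest$counts$clustered <- length(det$cluster)
    manifest$counts$dnb_members <- length(det$members)
    manifest$counts$panel <- length(panel_prot)
  }

  model <- NULL
  if ("score" %in% steps) {
    say("[score] DE filter + univariate Cox -> score model, median split, KM")
    sv <- read_survival(.cfg_path(config, "survival_file", "survival.csv"))
    ex <- read_expression(.cfg_path(config, "expression_file", "expression.csv"))
    ti <- utils::read.csv(.cfg_path(config, "tissue_file", "tissue.csv"),
                          stringsAsFactors = FALSE)
    cohort <- survival_cohort(sv$subject_id, sv$time, sv$event,
                              covariates = sv[, setdiff(names(sv),
                                                        c("subject_id", "time", "event")),
                                              drop = FALSE],
                              expression = ex,
                              tissue = stats::setNames(ti$tissue, ti$sample))
    panel_file <- file.path(config$out_dir, "dnb_panel.csv")
    panel <- if (file.exists(panel_file))
      utils::read.csv(panel_file, stringsAsFactors = FALSE)$protein_id
    else rownames(ex)
    # panel proteins map to genes by position in the synthetic design
    panel_genes <- intersect(rownames(ex), c(panel, gsub("^P", "G", panel)))
    if (length(panel_genes) == 0) panel_genes <- rownames(ex)
    model <- build_score_model(cohort, panel_genes,
                               alpha_fdr = config$alpha_fdr,
                               alpha_cox = config$alpha_cox, ties = config$ties)
    write_score_model(model, file.path(config$out_dir, "score_model"))
    scores <- score_subjects(model, cohort$expression[, cohort$subject_id,
                                                      drop = FALSE])
    grp <- median_stratify(scores)
    km <- km_logrank(cohort$time, cohort$event, grp)
    hr <- cox_multivariate(cohort, grp)
    write_report(list(km_curves = km$km, hazard_ratios = hr,
                      scores = data.frame(subject_id = names(scores),
                                          score = unname(scores),
                                          group = as.character(grp))),
                 config$out_dir)
    manifest$counts$de_selected <- sum(model$provenance$de_pass)
    manifest$counts$cox_selected <- sum(model$provenance$retained)
    manifest$counts$model_genes <- length(model$genes)
    manifest$logrank <- list(chisq = km$chisq, p = km$p)
  }

  if ("validate" %in% steps) {
    say("[validate] batch adjustment, scoring, response tabulation")
    if (is.null(model)) model <- read_score_model(file.path(config$out_dir,
                                                            "score_model"))
    vex_file <- .cfg_path(config, "validation_expression_file",
                          "validation_expression.csv")
    vresp_file <- .cfg_path(config, "validation_response_file",
                            "validation_response.csv")
    if (!file.exists(vex_file)) {
      val <- sim_validation_cohort(model, n_subjects = config$n_validation,
                                   batch_shift = config$batch_shift,
                                   response_link_strength = config$response_link_strength,
                                   seed = config$seed + 2L)
      utils::write.csv(data.frame(gene = rownames(val$expression),
                                  val$expression, check.names = FALSE),
                       vex_file, row.names = FALSE)
      utils::write.csv(data.frame(subject = names(val$response),
                                  response = unname(val$response)),
                       vresp_file, row.names = FALSE)
    }
    vex <- read_expression(vex_file)
    vresp <- utils::read.csv(vresp_file, stringsAsFactors = FALSE)
    ref <- read_expression(.cfg_path(config, "expression_file", "expression.csv"))
    common <- intersect(rownames(ref), rownames(vex))
    comb <- cbind(ref[common, , drop = FALSE], vex[common, , drop = FALSE])
    adj <- adjust_batches(comb, rep(c("reference", "validation"),
                                    c(ncol(ref), ncol(vex))), "reference")
    vadj <- adj[, colnames(vex), drop = FALSE]
    vscores <- score_subjects(model, vadj)
    vgrp <- median_stratify(vscores)
    tab <- response_tabulation(vgrp[vresp$subject], vresp$response)
    roc <- response_cutoff(vscores[vresp$subject],
                           vresp$response)
    utils::write.csv(tab, file.path(config$out_dir, "validation_tabulation.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(auc = roc$auc, cutoff = roc$cutoff),
                     file.path(config$out_dir, "validation_roc.csv"),
                     row.names = FALSE)
    manifest$validation <- list(auc = roc$auc, cutoff = roc$cutoff)
  }

  if ("clinical" %in% steps) {
    say("[clinical] RECIST calls, efficacy, safety, escalation")
    # fall back to the packaged reconstructed tables when no input is staged
    pick <- function(key, default) {
      p <- .cfg_path(config, key, default)
      if (file.exists(p)) p else system.file("extdata", default,
                                             package = "dnbscore")
    }
    lesions <- utils::read.csv(pick("lesions_file", "lesions_reconstructed.csv"),
                               stringsAsFactors = FALSE)
    teae <- utils::read.csv(pick("teae_file", "teae_listing_reconstructed.csv"),
                            stringsAsFactors = FALSE)
    recs <- call_responses(lesions)
    eff <- efficacy_table(recs)
    eff_df <- data.frame(n = eff$n, orr_pct = eff$orr_pct, dcr_pct = eff$dcr_pct)
    recs$gor_por <- stratify_gor_por(recs)
    safety <- teae_summary(teae, n_patients = eff$n)
    write_report(list(responses = recs, efficacy = eff_df,
                      teae_summary = safety), config$out_dir)
    manifest$efficacy <- list(orr_pct = eff$orr_pct, dcr_pct = eff$dcr_pct)
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  say("manifest written to ", manifest_path)
  invisible(manifest)
}
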