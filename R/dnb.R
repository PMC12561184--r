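POST_TIMEPOINTS <- c("D5", "DT", "LT")

# cross-patient SD of every protein at one time point; NA-tolerant,
# proteins observed in < min_n samples at that time point get NA
.tp_sd <- function(m, tp, min_n = 3) {
  cols <- samples_at(m, tp)
  if (length(cols) == 0) return(rep(NA_real_, nrow(m$values)))
  v <- m$values[, cols, drop = FALSE]
  n_obs <- rowSums(!is.na(v))
  s <- apply(v, 1, stats::sd, na.rm = TRUE)
  s[n_obs < min_n] <- NA_real_
  s
}

#' Variance-burst filter for DNB candidates
#'
#' Computes, for every protein, the cross-patient standard deviation at
#' each sampling time point and the ratio to the baseline (`D0`) SD. A
#' protein passes when its SD is at least `fold` times the baseline SD at
#' every post-baseline time point (the conjunctive reading of "each time
#' point"); `mode = "disjunctive"` relaxes this to at least one time
#' point. A protein with zero baseline SD but positive later SD has an
#' infinite ratio and passes; one flat everywhere fails. Proteins with
#' fewer than `min_n` observations at any required time point are dropped
#' from candidacy with a logged reason.
#'
#' @param m an [npx_matrix()] with the `LT` role assigned (see
#'   [assign_lt()]); the post-baseline time points are `D5`, `DT`, `LT`.
#' @param fold SD-ratio threshold (default two-fold).
#' @param mode `"conjunctive"` (all post-baseline time points, default) or
#'   `"disjunctive"` (any).
#' @param min_n minimum cross-patient observations per time point.
#' @return list with `candidates` (protein ids passing), `profile`
#'   (data.frame of per-time-point SDs and ratios) and `dropped`
#'   (low-coverage proteins).
#' @export
sd_filter <- function(m, fold = 2, mode = c("conjunctive", "disjunctive"),
                      min_n = 3) {
  stopifnot(inherits(m, "npx_matrix"))
  mode <- match.arg(mode)
  post <- POST_TIMEPOINTS[vapply(POST_TIMEPOINTS,
                                 function(tp) length(samples_at(m, tp)) > 0, logical(1))]
  if (length(post) == 0) stop("no post-baseline time points present")
  sd0 <- .tp_sd(m, "D0", min_n)
  sds <- vapply(post, function(tp) .tp_sd(m, tp, min_n), numeric(nrow(m$values)))
  sds <- matrix(sds, nrow = nrow(m$values),
                dimnames = list(rownames(m$values), post))
  ratio <- sds / sd0
  ratio[sd0 == 0 & sds > 0] <- Inf          # limit behaviour of the ratio
  ratio[sd0 == 0 & sds == 0] <- 0
  covered <- is.finite(sd0) | sd0 == 0
  covered <- !is.na(covered) & covered & apply(!is.na(sds), 1, all)
  dropped <- rownames(m$values)[!covered]
  pass <- if (mode == "conjunctive") apply(ratio >= fold, 1, all)
          else apply(ratio >= fold, 1, any)
  pass <- !is.na(pass) & pass & covered
  profile <- data.frame(protein_id = rownames(m$values), sd_d0 = sd0,
                        stringsAsFactors = FALSE)
  for (tp in post) {
    profile[[paste0("sd_", tolower(tp))]] <- sds[, tp]
    profile[[paste0("ratio_", tolower(tp))]] <- ratio[, tp]
  }
  profile$pass <- pass
  list(candidates = rownames(m$values)[pass], profile = profile,
       dropped = dropped, post_timepoints = post)
}

#' Standardize candidate temporal profiles
#'
#' Averages each candidate protein across patients at every time point
#' (D0 and the post-baseline points) and z-scores the resulting profile
#' across time points (mean 0, SD 1), so clustering sees shape, not level:
#' any affine transform of a profile maps to the same normalized profile.
#' Constant profiles cannot be standardized and are dropped with a
#' message.
#'
#' @param m an [npx_matrix()].
#' @param candidates protein ids to profile (non-empty).
#' @return matrix, candidates x time points, of z-scored mean profiles.
#' @export
normalize_trajectories <- function(m, candidates) {
  stopifnot(inherits(m, "npx_matrix"))
  if (length(candidates) == 0) stop("no candidate proteins")
  if (!all(candidates %in% rownames(m$values)))
    stop("unknown candidate protein(s)")
  tps <- c("D0", POST_TIMEPOINTS)
  tps <- tps[vapply(tps, function(tp) length(samples_at(m, tp)) > 0, logical(1))]
  prof <- vapply(tps, function(tp) {
    rowMeans(m$values[candidates, samples_at(m, tp), drop = FALSE], na.rm = TRUE)
  }, numeric(length(candidates)))
  prof <- matrix(prof, nrow = length(candidates),
                 dimnames = list(candidates, tps))
  sds <- apply(prof, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    message("dropping ", sum(flat), " constant profile(s): ",
            paste(utils::head(candidates[flat], 5), collapse = ", "))
    prof <- prof[!flat, , drop = FALSE]
  }
  if (nrow(prof) == 0) stop("all candidate profiles are constant")
  t(apply(prof, 1, function(z) (z - mean(z)) / stats::sd(z)))
}

#' Fuzzy c-means clustering of normalized profiles
#'
#' Soft clustering of the standardized temporal profiles (fuzzy c-means,
#' fuzzifier `m_fuzz`); membership rows sum to one and the hard
#' assignment is the argmax membership. Deterministic given `seed`.
#'
#' @param profiles matrix from [normalize_trajectories()].
#' @param c number of clusters, `2 <= c < nrow(profiles)`.
#' @param m_fuzz fuzzifier; values near 1 give near-crisp memberships,
#'   appropriate for short (4-point) profiles.
#' @param seed integer seed for the random initialization.
#' @return list with `membership` (proteins x c, rows sum to 1),
#'   `cluster` (named hard assignments) and `centers`.
#' @export
cluster_candidates <- function(profiles, c, m_fuzz = 1.25, seed = NULL) {
  if (!is.matrix(profiles) || nrow(profiles) < 3)
    stop("profiles must be a matrix with >= 3 rows")
  if (c < 2 || c >= nrow(profiles))
    stop("cluster count out of range: need 2 <= c < ", nrow(profiles))
  if (!is.null(seed)) set.seed(seed)
  fit <- e1071::cmeans(profiles, centers = c, m = m_fuzz, iter.max = 200)
  list(membership = fit$membership,
       cluster = stats::setNames(fit$cluster, rownames(profiles)),
       centers = fit$centers)
}

# Scan cluster counts and keep the best-separated fuzzy partition.
# Returns c = 1 (single merged cluster) when even the best partition has
# average silhouette width < sil_min, i.e. the candidates form one
# coherent profile cloud and any split would be an artifact.
.choose_clusters <- function(profiles, c_range = 2:8, m_fuzz = 1.25,
                             sil_min = 0.5, seed = NULL) {
  n <- nrow(profiles)
  c_range <- c_range[c_range >= 2 & c_range < n]
  if (n < 4 || length(c_range) == 0)
    return(list(c = 1L, cluster = stats::setNames(rep(1L, n), rownames(profiles)),
                sil = NA_real_))
  d <- stats::dist(profiles)
  best <- NULL
  for (cc in c_range) {
    cl <- cluster_candidates(profiles, cc, m_fuzz, seed = seed)
    if (length(unique(cl$cluster)) < 2) next
    sil <- mean(cluster::silhouette(cl$cluster, d)[, "sil_width"])
    if (is.null(best) || sil > best$sil)
      best <- list(c = cc, cluster = cl$cluster, membership = cl$membership,
                   sil = sil)
  }
  if (is.null(best) || best$sil < sil_min)
    return(list(c = 1L, cluster = stats::setNames(rep(1L, n), rownames(profiles)),
                sil = if (is.null(best)) NA_real_ else best$sil))
  best
}

# Shared engine for the four DNB indices and the permutation criteria.
# clusters: named list of member-id vectors. Computes, per cluster:
#   sd_avg   mean member SD over post-baseline time points
#   ppc_in   mean |pairwise Pearson r| among members, post-baseline pooled
#   ppc_out  mean |Pearson r| member vs non-member, post-baseline pooled
#   D0 reference values of both, permutation p-values for the PPCi change
#   and PPCo decrease (phase labels permuted across samples), and the
#   criticality index CI = sd_avg * ppc_in / max(ppc_out, eps).
.dnb_eval <- function(clusters, m, fold = 2, n_perm = 1000, alpha = 0.05,
                      eps = 1e-6, seed = NULL, min_pairs = 3) {
  stopifnot(inherits(m, "npx_matrix"))
  all_prot <- rownames(m$values)
  for (nm in names(clusters)) {
    mem <- clusters[[nm]]
    if (length(mem) < 2) stop("singleton cluster: ", nm)
    if (length(setdiff(all_prot, mem)) < 1)
      stop("cluster ", nm, " spans every protein; PPCo is undefined")
    if (!all(mem %in% all_prot)) stop("unknown member protein(s) in cluster ", nm)
  }
  post_cols <- unique(unlist(lapply(POST_TIMEPOINTS, function(tp) samples_at(m, tp))))
  d0_cols <- samples_at(m, "D0")
  if (length(post_cols) < min_pairs || length(d0_cols) < min_pairs)
    stop("fewer than ", min_pairs, " samples in a phase; correlations undefined")

  V <- m$values
  use <- if (anyNA(V)) "pairwise.complete.obs" else "everything"
  abs_cor <- function(cols) abs(stats::cor(t(V[, cols, drop = FALSE]), use = use))

  sf <- sd_filter(m, fold = fold, min_n = min_pairs)
  prof <- sf$profile
  ratio_cols <- grep("^ratio_", names(prof))
  sd_cols <- setdiff(grep("^sd_", names(prof)), grep("sd_d0", names(prof)))

  cluster_stats <- function(cin, cout, mem) {
    nonmem <- setdiff(all_prot, mem)
    win <- cin[mem, mem, drop = FALSE]
    ppc_in <- mean(win[upper.tri(win)], na.rm = TRUE)
    ppc_out <- mean(cin[mem, nonmem, drop = FALSE], na.rm = TRUE)
    win0 <- cout[mem, mem, drop = FALSE]
    ppc_in0 <- mean(win0[upper.tri(win0)], na.rm = TRUE)
    ppc_out0 <- mean(cout[mem, nonmem, drop = FALSE], na.rm = TRUE)
    c(ppc_in, ppc_out, ppc_in0, ppc_out0)
  }

  cor_post <- abs_cor(post_cols)
  cor_d0 <- abs_cor(d0_cols)
  obs <- lapply(clusters, function(mem) cluster_stats(cor_post, cor_d0, mem))

  n_d0 <- length(d0_cols)
  all_cols <- c(d0_cols, post_cols)
  ge_in <- le_out <- stats::setNames(numeric(length(clusters)), names(clusters))
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(n_perm)) {
      idx <- sample(all_cols)
      c0 <- abs_cor(idx[seq_len(n_d0)])
      c1 <- abs_cor(idx[-seq_len(n_d0)])
      for (i in seq_along(clusters)) {
        st <- cluster_stats(c1, c0, clusters[[i]])
        d_in_p <- st[1] - st[3]
        d_out_p <- st[2] - st[4]
        o <- obs[[i]]
        if (abs(d_in_p) >= abs(o[1] - o[3])) ge_in[i] <- ge_in[i] + 1
        if (d_out_p <= (o[2] - o[4])) le_out[i] <- le_out[i] + 1
      }
    }
  }

  reports <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    mem <- clusters[[i]]
    o <- obs[[i]]
    pr <- prof[match(mem, prof$protein_id), , drop = FALSE]
    sd_avg <- mean(as.matrix(pr[, sd_cols, drop = FALSE]), na.rm = TRUE)
    mean_ratio <- mean(as.matrix(pr[, ratio_cols, drop = FALSE]), na.rm = TRUE)
    p_in <- if (n_perm > 0) (1 + ge_in[i]) / (n_perm + 1) else NA_real_
    p_out <- if (n_perm > 0) (1 + le_out[i]) / (n_perm + 1) else NA_real_
    passes <- c(fluctuation = unname(mean_ratio >= fold),
                ppci_change = unname(!is.na(p_in) && p_in < alpha),
                ppco_decrease = unname(o[2] < o[4] && !is.na(p_out) && p_out < alpha))
    reports[[i]] <- structure(list(
      cluster_id = names(clusters)[i], members = mem,
      sd_avg = sd_avg, mean_sd_ratio = mean_ratio,
      ppc_in = o[1], ppc_out = o[2],
      ppc_in_d0 = o[3], ppc_out_d0 = o[4],
      p_ppci = unname(p_in), p_ppco = unname(p_out),
      passes_criteria = passes,
      ci = sd_avg * o[1] / max(o[2], eps)),
      class = "dnb_report")
  }
  names(reports) <- names(clusters)
  reports
}

#' Four DNB indices and criteria flags for one candidate cluster
#'
#' Computes the cluster's average member standard deviation (`sd_avg`,
#' over post-baseline time points), the mean absolute pairwise Pearson
#' correlation among members (`ppc_in`) and between members and all
#' non-member proteins (`ppc_out`), both on cross-patient values pooled
#' over the post-baseline time points (pairwise-complete when cells are
#' missing), and the criticality index
#' `CI = sd_avg * ppc_in / max(ppc_out, eps)`. Against the `D0`
#' reference it evaluates the three DNB criteria: (1) wide fluctuation
#' (mean SD ratio at least `fold`), (2) a significant change of `ppc_in`,
#' and (3) a significant decrease of `ppc_out`, the latter two by a
#' seeded permutation test of the phase labels (`n_perm` permutations,
#' level `alpha`).
#'
#' @param members cluster member protein ids (>= 2, and at least one
#'   non-member must remain).
#' @param m an [npx_matrix()] with `D0` and post-baseline samples.
#' @param fold fluctuation threshold on the mean SD ratio.
#' @param n_perm permutations for the correlation criteria (0 skips the
#'   tests).
#' @param alpha significance level for the permutation criteria.
#' @param eps floor applied to `ppc_out` in the CI denominator.
#' @param seed integer seed for the permutations.
#' @return An object of class `dnb_report`.
#' @export
dnb_indices <- function(members, m, fold = 2, n_perm = 1000, alpha = 0.05,
                        eps = 1e-6, seed = NULL) {
  .dnb_eval(list(cluster = members), m, fold = fold, n_perm = n_perm,
            alpha = alpha, eps = eps, seed = seed)[[1L]]
}

#' @export
print.dnb_report <- function(x, ...) {
  cat("DNB cluster", x$cluster_id, "(", length(x$members), "proteins )\n")
  cat(sprintf("  SDavg = %.3f  PPCi = %.3f  PPCo = %.3f  CI = %.3f\n",
              x$sd_avg, x$ppc_in, x$ppc_out, x$ci))
  cat(sprintf("  D0 reference: PPCi = %.3f  PPCo = %.3f\n",
              x$ppc_in_d0, x$ppc_out_d0))
  ok <- x$passes_criteria
  cat("  criteria:", paste(names(ok), ifelse(ok, "pass", "fail"),
                           sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Pick the winning DNB cluster
#'
#' Among clusters whose three criteria flags all hold, the one with the
#' largest criticality index wins; ties break toward the larger
#' membership, then the lexicographically smallest cluster id. When no
#' cluster passes all criteria the maximum-CI cluster is returned with a
#' prominent warning.
#'
#' @param reports list of `dnb_report` objects (non-empty).
#' @return The winning `dnb_report`.
#' @export
select_dnb <- function(reports) {
  if (inherits(reports, "dnb_report")) reports <- list(reports)
  if (length(reports) == 0) stop("empty report list")
  ok <- vapply(reports, function(r) all(r$passes_criteria), logical(1))
  pool <- if (any(ok)) reports[ok] else reports
  if (!any(ok))
    warning("no cluster passes all three DNB criteria; returning the maximum-CI cluster")
  ci <- vapply(pool, function(r) r$ci, numeric(1))
  size <- vapply(pool, function(r) length(r$members), numeric(1))
  id <- vapply(pool, function(r) r$cluster_id, character(1))
  ord <- order(-ci, -size, id)
  pool[[ord[1L]]]
}

#' Intersect the DNB cluster with the PLS-DA selection
#'
#' The DNB panel is the exact overlap of the winning cluster's members and
#' the VIP-selected proteins; an empty overlap is allowed but warned
#' about.
#'
#' @param dnb_members winning-cluster protein ids (non-empty).
#' @param plsda_selection VIP-selected protein ids, or a data.frame from
#'   [select_vip()].
#' @param provenance optional character notes (contrast, cluster id).
#' @return list with `proteins` (the panel) and `provenance`.
#' @export
build_panel <- function(dnb_members, plsda_selection, provenance = NULL) {
  if (is.data.frame(plsda_selection)) plsda_selection <- plsda_selection$protein_id
  if (length(dnb_members) == 0 || length(plsda_selection) == 0)
    stop("both input sets must be non-empty")
  panel <- intersect(dnb_members, plsda_selection)
  if (length(panel) == 0)
    warning("DNB cluster and PLS-DA selection are disjoint: empty panel")
  list(proteins = panel, provenance = provenance)
}

#' End-to-end DNB detection
#'
#' Runs the four-step identification on a longitudinal NPX matrix:
#' (1) the two-fold variance-burst filter against baseline
#' ([sd_filter()]); (2) standardization of the surviving temporal
#' profiles ([normalize_trajectories()]); (3) fuzzy c-means clustering,
#' with the cluster count chosen by scanning `c_range` for the best
#' average silhouette width and falling back to a single merged cluster
#' when no partition reaches `sil_min` (candidates forming one coherent
#' profile cloud are one DNB candidate, not several); (4) the four
#' indices, permutation criteria and criteria-gated maximum-CI selection
#' ([dnb_indices()], [select_dnb()]).
#'
#' @param m an [npx_matrix()]; run [assign_lt()] first if the last-time
#'   role is not yet set.
#' @param fold SD-ratio threshold of the filter.
#' @param sd_mode conjunctive (default) or disjunctive filter reading.
#' @param c_range cluster counts scanned.
#' @param m_fuzz fuzzy c-means fuzzifier.
#' @param sil_min minimum average silhouette width for accepting a
#'   multi-cluster partition.
#' @param n_perm,alpha permutation settings for the criteria.
#' @param eps CI denominator floor.
#' @param seed integer seed (clustering initialization and permutations).
#' @return Object of class `dnb` with the filter output, clustering, all
#'   cluster reports and the `winner`.
#' @export
dnb_detect <- function(m, fold = 2, sd_mode = "conjunctive", c_range = 2:8,
                       m_fuzz = 1.25, sil_min = 0.5, n_perm = 1000,
                       alpha = 0.05, eps = 1e-6, seed = 1) {
  stopifnot(inherits(m, "npx_matrix"))
  sf <- sd_filter(m, fold = fold, mode = sd_mode)
  if (length(sf$candidates) < 2)
    stop("fewer than 2 proteins pass the SD filter; no cluster to evaluate")
  prof <- normalize_trajectories(m, sf$candidates)
  ch <- .choose_clusters(prof, c_range = c_range, m_fuzz = m_fuzz,
                         sil_min = sil_min, seed = seed)
  clusters <- split(names(ch$cluster), ch$cluster)
  names(clusters) <- sprintf("C%d", as.integer(names(clusters)))
  clusters <- clusters[vapply(clusters, length, integer(1)) >= 2]
  if (length(clusters) == 0) stop("all clusters are singletons")
  reports <- .dnb_eval(clusters, m, fold = fold, n_perm = n_perm,
                       alpha = alpha, eps = eps, seed = seed)
  winner <- select_dnb(reports)
  structure(list(filter = sf, profiles = prof, n_clusters = ch$c,
                 silhouette = ch$sil, cluster = ch$cluster,
                 reports = reports, winner = winner,
                 members = winner$members,
                 settings = list(fold = fold, sd_mode = sd_mode,
                                 c_range = c_range, m_fuzz = m_fuzz,
                                 sil_min = sil_min, n_perm = n_perm,
                                 alpha = alpha, eps = eps, seed = seed)),
            class = "dnb")
}

#' @export
print.dnb <- function(x, ...) {
  cat("DNB detection:", length(x$filter$candidates), "of",
      nrow(x$filter$profile), "proteins pass the", x$settings$fold,
      "x SD filter\n")
  cat("  clusters:", x$n_clusters,
      if (x$n_clusters > 1) sprintf("(avg silhouette %.2f)", x$silhouette)
      else "(merged: no separable profile structure)", "\n")
  cat("  winning cluster:\n")
  print(x$winner)
  invisible(x)
}

#' @export
summary.dnb <- function(object, ...) {
  print(object)
  cat("\nAll cluster reports:\n")
  for (r in object$reports) print(r)
  invisible(object)
}

#' @export
plot.dnb <- function(x, ...) {
  prof <- x$profiles
  cl <- x$cluster[rownames(prof)]
  win <- rownames(prof) %in% x$members
  graphics::matplot(t(prof), type = "l", lty = 1,
                    col = ifelse(win, "firebrick", "grey60"),
                    xaxt = "n", xlab = "time point",
                    ylab = "standardized mean NPX",
                    main = "Candidate trajectories (winning DNB in red)", ...)
  graphics::axis(1, at = seq_len(ncol(prof)), labels = colnames(prof))
  invisible(x)
}
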