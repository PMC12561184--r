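#' Two-class PLS-DA with VIP scoring
#'
#' Fits a partial least squares discriminant model by NIPALS on
#' column-centered, unit-variance-scaled data, with the class encoded as a
#' single centered 0/1 response. Per component `a` the unit-norm weight
#' vector `w_a`, scores `t_a = X_a w_a`, X-loadings `p_a` and y-loading
#' `q_a` are extracted and the matrices deflated. The variance of the
#' class response explained by component `a` is `SS_a = q_a^2 t_a't_a`,
#' and each protein's variable importance in projection is
#' `VIP_j = sqrt(p * sum_a(SS_a w_aj^2) / sum_a(SS_a))`, so
#' `sum_j VIP_j^2 = p` exactly. Proteins with `VIP >= 1` are conventionally
#' read as contributing more than average to the class separation.
#'
#' Missing cells are mean-imputed per protein before the fit (NIPALS as
#' implemented here requires complete columns); the imputation count is
#' recorded on the returned object. Components whose residual response
#' variance vanishes are not extracted, so the fitted number of components
#' can be smaller than requested.
#'
#' @param x protein x sample numeric matrix.
#' @param y class label per sample; exactly two levels, each with at least
#'   two samples.
#' @param ncomp number of latent components requested.
#' @return Object of class `plsda` with elements `weights` (p x A),
#'   `loadings`, `scores`, `q`, `ssy` (per-component explained response
#'   SS), `vip`, `r2x`, `r2y`, the scaling parameters and class levels.
#' @seealso [select_vip()], [run_group_contrasts()]
#' @export
plsda <- function(x, y, ncomp = 2) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric protein x sample matrix")
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes, got ", nlevels(y))
  if (any(table(y) < 2)) stop("each class needs >= 2 samples")
  if (length(y) != ncol(x)) stop("length(y) must equal ncol(x)")

  X <- t(x)                                     # samples x proteins
  n_imputed <- 0L
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      na <- is.na(X[, j])
      if (any(na)) {
        if (all(na)) stop("protein with no observed values: ", colnames(X)[j])
        X[na, j] <- mean(X[!na, j])
        n_imputed <- n_imputed + sum(na)
      }
    }
  }
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("no proteins with non-zero variance left to fit")
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  centers <- colMeans(X)
  scales <- sds[keep]
  X <- sweep(sweep(X, 2, centers), 2, scales, "/")
  p <- ncol(X)
  n <- nrow(X)

  y_num <- as.numeric(y) - 1                    # 0/1 coding
  y_mean <- mean(y_num)
  yc <- y_num - y_mean
  ss_x_tot <- sum(X^2)
  ss_y_tot <- sum(yc^2)

  A <- min(ncomp, p, n - 1)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- ssy <- r2x <- numeric(A)
  Xa <- X; ya <- yc
  a_fit <- 0L
  for (a in seq_len(A)) {
    wv <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12 || sum(ya^2) < 1e-12 * ss_y_tot) break
    wv <- wv / nw
    tv <- drop(Xa %*% wv)
    tt <- sum(tv^2)
    pv <- drop(crossprod(Xa, tv)) / tt
    qa <- sum(ya * tv) / tt
    Xa <- Xa - tcrossprod(tv, pv)
    ya <- ya - tv * qa
    a_fit <- a
    W[, a] <- wv; P[, a] <- pv; Tm[, a] <- tv
    q[a] <- qa
    ssy[a] <- qa^2 * tt
    r2x[a] <- tt * sum(pv^2) / ss_x_tot
  }
  if (a_fit == 0L) stop("no component could be extracted (response orthogonal to data)")
  idx <- seq_len(a_fit)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Tm <- Tm[, idx, drop = FALSE]
  q <- q[idx]; ssy <- ssy[idx]; r2x <- r2x[idx]
  rownames(W) <- rownames(P) <- colnames(X)

  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X)

  structure(list(ncomp = a_fit, weights = W, loadings = P, scores = Tm,
                 q = q, ssy = ssy, vip = vip,
                 r2x = r2x, r2y = ssy / ss_y_tot,
                 centers = centers, scales = scales, y_mean = y_mean,
                 levels = levels(y), y = y, dropped = dropped,
                 n_imputed = n_imputed),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model:", length(x$vip), "proteins,", x$ncomp, "component(s),",
      "classes", paste(x$levels, collapse = " vs "), "\n")
  cat("  R2X =", paste(signif(x$r2x, 3), collapse = " + "),
      " R2Y =", paste(signif(x$r2y, 3), collapse = " + "), "\n")
  cat("  proteins with VIP >= 1:", sum(x$vip >= 1), "\n")
  if (x$n_imputed > 0) cat("  imputed cells:", x$n_imputed, "\n")
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  print(object)
  cat("\nTop VIP proteins:\n")
  print(utils::head(sort(object$vip, decreasing = TRUE), 10))
  invisible(object)
}

#' @export
coef.plsda <- function(object, ...) {
  W <- object$weights
  # standard PLS regression coefficients on the autoscaled space
  drop(W %*% solve(crossprod(object$loadings, W), object$q))
}

#' @export
predict.plsda <- function(object, newdata, type = c("class", "response"), ...) {
  type <- match.arg(type)
  X <- t(newdata)[, names(object$vip), drop = FALSE]
  X <- sweep(sweep(X, 2, object$centers), 2, object$scales, "/")
  yhat <- drop(X %*% coef(object)) + object$y_mean
  if (type == "response") return(yhat)
  factor(object$levels[(yhat > 0.5) + 1L], levels = object$levels)
}

#' @export
plot.plsda <- function(x, ...) {
  if (x$ncomp >= 2) {
    graphics::plot(x$scores[, 1], x$scores[, 2],
                   col = as.integer(x$y), pch = 19,
                   xlab = "t1", ylab = "t2", main = "PLS-DA scores", ...)
    graphics::legend("topright", legend = x$levels, col = 1:2, pch = 19)
  } else {
    graphics::stripchart(x$scores[, 1] ~ x$y, vertical = TRUE, pch = 19,
                         ylab = "t1", main = "PLS-DA scores", ...)
  }
  invisible(x)
}

#' Extract VIP scores
#' @param model a fitted [plsda()] model.
#' @return named numeric vector of VIP values.
#' @export
vip <- function(model) {
  if (!inherits(model, "plsda")) stop("`model` must be a plsda fit")
  model$vip
}

#' Select proteins by VIP threshold
#'
#' Returns the proteins whose VIP reaches the threshold (inclusive, i.e.
#' `VIP >= threshold`), with their VIP values for reporting.
#'
#' @param model a fitted [plsda()] model.
#' @param threshold inclusive VIP cutoff; `0` selects everything.
#' @return data.frame with columns `protein_id`, `vip`, ordered by
#'   decreasing VIP.
#' @export
select_vip <- function(model, threshold = 1) {
  if (!inherits(model, "plsda") || length(model$vip) == 0)
    stop("`model` must be a fitted plsda model with at least one protein")
  v <- sort(model$vip[model$vip >= threshold], decreasing = TRUE)
  data.frame(protein_id = names(v), vip = unname(v), stringsAsFactors = FALSE)
}

#' Run the two response-group PLS-DA contrasts
#'
#' Fits GoR-vs-PoR discriminant models on (i) baseline `D0` samples only
#' and (ii) all collected samples with a labelled patient (each sample
#' weighted equally, no per-patient aggregation), and returns the
#' VIP-selected protein set of each contrast together with the fitted
#' models.
#'
#' @param m an [npx_matrix()] with `GoR`/`PoR` patient labels.
#' @param ncomp components per model.
#' @param threshold inclusive VIP selection cutoff.
#' @return list with elements `d0` and `all`, each holding `model`,
#'   `selection` (as from [select_vip()]) and the sample count used.
#' @export
run_group_contrasts <- function(m, ncomp = 2, threshold = 1) {
  stopifnot(inherits(m, "npx_matrix"))
  sm <- m$sample_meta
  grp <- m$patient_meta$group[match(sm$patient_id, m$patient_meta$patient_id)]
  labelled <- grp %in% c("GoR", "PoR")
  if (!any(labelled)) stop("no samples with a GoR/PoR patient label")
  fit_one <- function(cols) {
    y <- grp[match(cols, sm$sample_id)]
    if (length(unique(y)) < 2 || any(table(y) < 2))
      stop("contrast needs >= 2 samples in each class")
    model <- plsda(m$values[, cols, drop = FALSE], factor(y, c("GoR", "PoR")),
                   ncomp = ncomp)
    list(model = model, selection = select_vip(model, threshold),
         n_samples = length(cols))
  }
  d0_cols <- intersect(samples_at(m, "D0"), sm$sample_id[labelled])
  all_cols <- sm$sample_id[labelled]
  list(d0 = fit_one(d0_cols), all = fit_one(all_cols))
}
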