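# Independent oracles used to cross-check the package implementations.
# Each is written directly from the defining formula, not from the package
# code path it checks.

# From-scratch NIPALS PLS1 with VIP, on autoscaled data and a centered 0/1
# response. Returns the VIP vector and per-component weights.
nipals_vip_oracle <- function(x, y01, ncomp = 2) {
  X <- scale(t(x))                       # samples x proteins, autoscaled
  y <- y01 - mean(y01)
  p <- ncol(X)
  W <- matrix(0, p, ncomp)
  ss <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- as.numeric(crossprod(X, y))
    w <- w / sqrt(sum(w^2))
    tt <- as.numeric(X %*% w)
    pp <- as.numeric(crossprod(X, tt)) / sum(tt^2)
    qq <- sum(y * tt) / sum(tt^2)
    ss[a] <- qq^2 * sum(tt^2)
    X <- X - outer(tt, pp)
    y <- y - qq * tt
    W[, a] <- w
  }
  vip <- vapply(seq_len(p), function(j) sqrt(p * sum(ss * W[j, ]^2) / sum(ss)),
                numeric(1))
  names(vip) <- rownames(x)
  list(vip = vip, weights = W, ss = ss)
}

# Breslow log partial likelihood maximized by two-stage grid search.
cox_grid_oracle <- function(time, event, x) {
  lpl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  grid <- seq(-5, 5, by = 0.001)
  b0 <- grid[which.max(vapply(grid, lpl, numeric(1)))]
  fine <- seq(b0 - 0.002, b0 + 0.002, by = 1e-5)
  fine[which.max(vapply(fine, lpl, numeric(1)))]
}

# Hand product-limit estimator: survival after each distinct event time.
km_hand_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = ut, survival = out)
}

# Monte-Carlo sampling distribution of the SD ratio: ratio of two
# independent sample SDs (n patients each) with true ratio `a`.
sd_ratio_band <- function(a = 3, n = 40, reps = 10000, probs = c(0.01, 0.99),
                          seed = 424242) {
  set.seed(seed)
  r <- replicate(reps, a * stats::sd(stats::rnorm(n)) / stats::sd(stats::rnorm(n)))
  stats::quantile(r, probs)
}

# Small complete longitudinal fixture: 2 patients x timepoints x proteins.
toy_npx <- function(patients = c("A", "B"), tps = c("D0", "D5"),
                    proteins = c("P1", "P2", "P3"), values = NULL) {
  ids <- as.vector(outer(patients, tps, paste, sep = "_"))
  if (is.null(values))
    values <- matrix(seq_len(length(proteins) * length(ids)),
                     nrow = length(proteins))
  dimnames(values) <- list(proteins, ids)
  sm <- data.frame(sample_id = ids,
                   patient_id = rep(patients, times = length(tps)),
                   timepoint = rep(tps, each = length(patients)))
  npx_matrix(values, sm)
}
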