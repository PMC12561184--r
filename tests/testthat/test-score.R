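toy_cohort <- function(time, event, x, gene = "G1") {
  expr <- matrix(x, 1, dimnames = list(gene, paste0("s", seq_along(x))))
  survival_cohort(colnames(expr), time, event, expression = expr,
                  covariates = data.frame(age = seq_along(x) + 50,
                                          stage = rep(1:2, length.out = length(x))))
}

test_that("DE filter selects shifted genes and leaves identical ones", {
  sim <- sim_survival_cohort(n_subjects = 100, n_normal = 100, n_genes = 30,
                             de_genes = sprintf("G%03d", 1:6), de_shift = 2,
                             seed = 8)
  co <- sim$cohort
  co$expression["G030", ] <- rep(c(1, 2, 3, 4), length.out = ncol(co$expression))
  de <- de_filter(co)
  expect_true(all(sprintf("G%03d", 1:6) %in% de$selected))
  expect_false("G030" %in% de$selected)
})

test_that("a cleanly separated gene attains the extreme rank-sum statistic", {
  set.seed(1)
  tum <- rnorm(10) + 10; nor <- rnorm(10)
  expr <- matrix(c(tum, nor, rnorm(20)), 2, byrow = TRUE,
                 dimnames = list(c("Gsep", "Gnull"), paste0("s", 1:20)))
  co <- survival_cohort(paste0("s", 1:10), time = 1:10, event = rep(1, 10),
                        expression = expr,
                        tissue = setNames(rep(c("tumor", "normal"), each = 10),
                                          paste0("s", 1:20)))
  de <- de_filter(co)
  expect_true("Gsep" %in% de$selected)
  w <- wilcox.test(tum, nor, exact = TRUE)
  expect_equal(unname(w$statistic), 100)           # all tumor > all normal
})

test_that("univariate Cox matches the grid-search partial likelihood oracle", {
  time <- 1:6; event <- rep(1, 6); x <- c(1, 0, 1, 0, 1, 0)
  co <- toy_cohort(time, event, x)
  fit <- suppressWarnings(cox_univariate(co, "G1"))
  expect_equal(fit$beta, cox_grid_oracle(time, event, x), tolerance = 1e-4)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-12)
})

test_that("Cox handles constant covariates and recovers a planted effect", {
  co <- toy_cohort(1:12, rep(1, 12), rep(2, 12))
  fit <- cox_univariate(co, "G1")
  expect_equal(fit$beta, 0)
  expect_equal(fit$flag, "constant covariate")

  sim <- sim_survival_cohort(n_subjects = 1000, n_genes = 5,
                             true_betas = c(0.7, 0, 0, 0, 0),
                             n_normal = 0, seed = 77)
  est <- cox_univariate(sim$cohort, "G001")
  expect_lt(abs(est$beta - 0.7), 0.15)
})

test_that("the score model composes the DE and Cox filters", {
  sim <- sim_survival_cohort(n_subjects = 300, n_genes = 12, seed = 5)
  # truth: betas on G001-G003, DE shift on G001-G005
  model <- build_score_model(sim$cohort, sprintf("G%03d", 1:12))
  expect_true(all(model$genes %in% sprintf("G%03d", 1:5)))   # DE gate
  expect_true(all(sprintf("G%03d", 1:3) %in% model$genes))   # Cox gate keeps truth
  prov <- model$provenance
  expect_equal(sum(prov$retained), length(model$genes))
  expect_error(build_score_model(sim$cohort, character()), "empty")
  expect_warning(
    expect_error(build_score_model(sim$cohort, "NOPE"), "no panel gene"),
    "absent")
  # serialization round trip is bit-identical for the coefficients
  base <- file.path(withr::local_tempdir(), "model")
  write_score_model(model, base)
  back <- read_score_model(base)
  expect_identical(back$betas, model$betas)
  expect_identical(back$genes, model$genes)
})

test_that("scores are linear, order-invariant and strict about genes", {
  model <- structure(list(genes = c("a", "b"),
                          betas = c(a = 0.5, b = -0.2)), class = "score_model")
  expr <- matrix(c(2, 1), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(score_subjects(model, expr)), 0.8)
  expect_equal(unname(score_subjects(model, expr * 2)), 1.6)  # linearity
  expect_equal(score_subjects(model, expr[c("b", "a"), , drop = FALSE]),
               score_subjects(model, expr))                  # gene order
  zero <- model; zero$betas[] <- 0
  expect_equal(unname(score_subjects(zero, expr)), 0)
  expect_error(score_subjects(model, expr["a", , drop = FALSE]), "lacks")
})

test_that("median stratification puts the median subject in the low group", {
  g <- median_stratify(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g2 <- median_stratify(c(1, 2, 3))           # subject at the median is low
  expect_equal(as.character(g2), c("low", "low", "high"))
  expect_error(median_stratify(c(5, 5, 5)), "identical")
  expect_error(median_stratify(7), ">= 2")
})

test_that("KM steps match the hand-computed product-limit values", {
  time <- c(1:6, 1:6); event <- c(1, 1, 0, 1, 0, 1, 1, 1, 0, 1, 0, 1)
  group <- rep(c("a", "b"), each = 6)
  res <- km_logrank(time, event, group)
  hand <- km_hand_oracle(time[1:6], event[1:6])
  got <- res$km[res$km$group == "a" & res$km$n_event > 0, ]
  expect_equal(got$time, hand$time)
  expect_equal(got$survival, hand$survival, tolerance = 1e-12)
  # identical groups: no separation
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # survival curves start below 1 only after events and never increase
  for (g in c("a", "b"))
    expect_true(all(diff(res$km$survival[res$km$group == g]) <= 1e-12))
})

test_that("with no censoring KM equals the empirical survival function", {
  set.seed(2)
  t1 <- rexp(30); t2 <- rexp(30, 2)
  res <- km_logrank(c(t1, t2), rep(1, 60), rep(c("a", "b"), each = 30))
  ka <- res$km[res$km$group == "a", ]
  expect_equal(ka$survival, 1 - ecdf(t1)(ka$time), tolerance = 1e-12)
})

test_that("multivariate Cox isolates the score effect and flags collinearity", {
  sim <- sim_survival_cohort(n_subjects = 600, n_genes = 5,
                             true_betas = c(0.8, 0, 0, 0, 0),
                             n_normal = 0, seed = 41)
  co <- sim$cohort
  scores <- co$expression["G001", co$subject_id]
  grp <- median_stratify(scores)
  hr <- cox_multivariate(co, grp)
  expect_gt(hr$hr[hr$term == "score_grouphigh"], 1.5)
  expect_lt(hr$p[hr$term == "score_grouphigh"], 0.001)
  # age/stage were generated independently of survival
  expect_gt(hr$p[hr$term == "age"], 0.001)
  co$covariates$age2 <- co$covariates$age
  expect_error(cox_multivariate(co, grp, covariates = c("age", "age2")),
               "collinear")
})

test_that("ROC cutoff separates classes and handles the null", {
  sc <- c(rnorm(20, 0), rnorm(20, 10))
  resp <- rep(c(TRUE, FALSE), each = 20)   # low scores respond
  rc <- response_cutoff(sc, resp)
  expect_equal(rc$auc, 1)
  expect_gt(rc$cutoff, max(sc[resp]))
  expect_lt(rc$cutoff, min(sc[!resp]))
  expect_error(response_cutoff(sc, rep(TRUE, 40)), "both response classes")
  # labels independent of scores: AUC near one half
  set.seed(33)
  auc0 <- replicate(20, response_cutoff(rnorm(200),
                                        sample(c(TRUE, FALSE), 200, TRUE))$auc)
  expect_lt(abs(mean(auc0) - 0.5), 0.03)
})

test_that("Spearman correlations behave at the monotone extremes", {
  set.seed(4)
  scores <- setNames(rnorm(10), paste0("s", 1:10))
  fr <- rbind(mono = exp(scores), anti = -scores^3)
  colnames(fr) <- names(scores)
  res <- fraction_correlation(scores, fr)
  expect_equal(res$rho[res$cell_type == "mono"], 1)
  expect_equal(res$rho[res$cell_type == "anti"], -1)
  expect_equal(cor(c(1, 2, 3), c(3, 2, 1), method = "spearman"), -1)
})

test_that("the score chain detects planted hazard separation", {
  sim <- sim_survival_cohort(n_subjects = 400, seed = 19)
  model <- build_score_model(sim$cohort, sprintf("G%03d", 1:12))
  sc <- score_subjects(model, sim$cohort$expression[, sim$cohort$subject_id])
  grp <- median_stratify(sc)
  km <- km_logrank(sim$cohort$time, sim$cohort$event, grp)
  expect_lt(km$p, 0.01)
  # high-score group has worse survival: lower curve at the median time
  med_t <- median(sim$cohort$time)
  tail_surv <- sapply(c("low", "high"), function(g) {
    kg <- km$km[km$km$group == g & km$km$time <= med_t, ]
    kg$survival[nrow(kg)]
  })
  expect_gt(tail_surv["low"], tail_surv["high"])
})
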