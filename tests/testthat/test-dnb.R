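# longitudinal fixture with hand-set per-timepoint SDs for one protein
sd_fixture <- function(sds, n = 20, seed = 1) {
  set.seed(seed)
  tps <- c("D0", "D5", "DT", "LT")
  vals <- do.call(cbind, lapply(seq_along(tps), function(k) {
    v <- rbind(as.numeric(scale(rnorm(n))) * sds[k],   # exact sample SD
               matrix(rnorm(2 * n), 2))
    colnames(v) <- paste0("PT", seq_len(n), "_", tps[k])
    v
  }))
  rownames(vals) <- c("target", "bg1", "bg2")
  sm <- data.frame(sample_id = colnames(vals),
                   patient_id = rep(paste0("PT", seq_len(n)), times = 4),
                   timepoint = rep(tps, each = n))
  npx_matrix(vals, sm)
}

test_that("SD filter applies the fold rule at every post-baseline time point", {
  m <- sd_fixture(c(1, 2.5, 3, 2.1))
  sf <- sd_filter(m)
  expect_true("target" %in% sf$candidates)
  prof <- sf$profile[sf$profile$protein_id == "target", ]
  expect_equal(prof$ratio_d5, 2.5, tolerance = 1e-10)

  m2 <- sd_fixture(c(1, 2.5, 1.9, 3))
  expect_false("target" %in% sd_filter(m2)$candidates)        # DT ratio 1.9 < 2
  expect_true("target" %in%
                sd_filter(m2, mode = "disjunctive")$candidates)

  # fold sweep is monotone non-increasing
  counts <- sapply(c(1, 1.5, 2, 2.5, 3), function(f)
    length(sd_filter(m, fold = f)$candidates))
  expect_true(all(diff(counts) <= 0))
})

test_that("zero baseline SD follows the ratio's limit behaviour", {
  m <- sd_fixture(c(1, 3, 3, 3))
  m$values["target", samples_at(m, "D0")] <- 5        # flat at baseline
  sf <- sd_filter(m)
  expect_true("target" %in% sf$candidates)            # ratio +Inf passes
  for (tp in c("D5", "DT", "LT"))
    m$values["target", samples_at(m, tp)] <- 5        # flat everywhere
  expect_false("target" %in% sd_filter(m)$candidates)
})

test_that("trajectory normalization z-scores shape and drops constants", {
  m <- sd_fixture(c(1, 2.5, 3, 2.1))
  # overwrite means: target rises 1,2,3,4 across time points
  for (k in seq_along(c("D0", "D5", "DT", "LT")))
    m$values["bg1", samples_at(m, c("D0", "D5", "DT", "LT")[k])] <- k
  prof <- normalize_trajectories(m, c("target", "bg1"))
  expect_equal(unname(rowMeans(prof)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(prof, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(prof["bg1", ]), scale(1:4)[, 1], tolerance = 1e-12)
  # affine transforms map to the same normalized profile
  m2 <- m
  m2$values["bg1", ] <- 3 * m2$values["bg1", ] - 7
  prof2 <- normalize_trajectories(m2, "bg1")
  expect_equal(prof2["bg1", ], prof["bg1", ], tolerance = 1e-12)
  # constant profiles are dropped
  m$values["bg2", ] <- 1
  expect_message(p3 <- normalize_trajectories(m, c("target", "bg2")), "constant")
  expect_equal(rownames(p3), "target")
})

test_that("fuzzy memberships sum to one and recover planted profile shapes", {
  rise <- c(-1.2, -0.4, 0.4, 1.2); fall <- rev(rise)
  agree <- sapply(1:20, function(s) {
    set.seed(s)
    prof <- rbind(t(sapply(1:8, function(i) rise + rnorm(4, 0, 0.3))),
                  t(sapply(1:8, function(i) fall + rnorm(4, 0, 0.3))))
    rownames(prof) <- sprintf("P%02d", 1:16)
    prof <- t(apply(prof, 1, function(z) (z - mean(z)) / sd(z)))
    cl <- cluster_candidates(prof, 2, seed = s)
    expect_equal(unname(rowSums(cl$membership)), rep(1, 16), tolerance = 1e-8)
    truth <- rep(1:2, each = 8)
    max(mean(cl$cluster == truth), mean(cl$cluster == 3 - truth))
  })
  expect_gte(mean(agree >= 0.95), 0.95)
  # same seed, same memberships
  set.seed(1)
  prof <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("P", 1:10), NULL))
  c1 <- cluster_candidates(prof, 2, seed = 11)
  c2 <- cluster_candidates(prof, 2, seed = 11)
  expect_identical(c1$membership, c2$membership)
  expect_error(cluster_candidates(prof, 1), "out of range")
  expect_error(cluster_candidates(prof, 10), "out of range")
})

test_that("the criticality index composes the three indices as stated", {
  # CI = sd_avg * ppc_in / ppc_out on a report with known ingredients
  r <- structure(list(cluster_id = "C1", members = c("a", "b"),
                      sd_avg = 2, ppc_in = 0.8, ppc_out = 0.4,
                      passes_criteria = c(TRUE, TRUE, TRUE),
                      ci = 2 * 0.8 / 0.4), class = "dnb_report")
  expect_equal(r$ci, 4)
  # computed end to end on a tiny cohort with a near-perfectly correlated pair
  sim <- sim_longitudinal_npx(n_patients = 30, n_proteins = 10, n_planted = 2,
                              rho_in = 0.999, rho_out = 0, effect_shift = 0,
                              seed = 15)
  rep2 <- dnb_indices(sim$truth$planted, sim$npx, n_perm = 0)
  expect_gt(rep2$ppc_in, 0.99)
  expect_equal(rep2$ci, rep2$sd_avg * rep2$ppc_in / max(rep2$ppc_out, 1e-6),
               tolerance = 1e-12)
})

test_that("index computation rejects degenerate clusters", {
  sim <- sim_longitudinal_npx(n_patients = 10, n_proteins = 6, n_planted = 2,
                              seed = 2)
  expect_error(dnb_indices("P001", sim$npx), "singleton")
  expect_error(dnb_indices(rownames(sim$npx$values), sim$npx), "every protein")
})

test_that("select_dnb gates on criteria before taking the maximum CI", {
  mk <- function(id, ci, pass, n = 5)
    structure(list(cluster_id = id, members = paste0(id, seq_len(n)),
                   sd_avg = 1, ppc_in = 0.5, ppc_out = 0.1,
                   passes_criteria = c(fluctuation = pass, ppci_change = pass,
                                       ppco_decrease = pass), ci = ci),
              class = "dnb_report")
  picked <- select_dnb(list(mk("A", 4.0, TRUE), mk("B", 7.2, TRUE),
                            mk("C", 9.9, FALSE)))
  expect_equal(picked$cluster_id, "B")
  expect_equal(select_dnb(list(mk("A", 4, TRUE)))$cluster_id, "A")
  expect_warning(w <- select_dnb(list(mk("C", 9.9, FALSE), mk("D", 3, FALSE))),
                 "no cluster passes")
  expect_equal(w$cluster_id, "C")
  # tie-break: larger membership first, then lexicographic id
  tie <- select_dnb(list(mk("B", 5, TRUE, n = 3), mk("A", 5, TRUE, n = 6)))
  expect_equal(tie$cluster_id, "A")
  expect_error(select_dnb(list()), "empty")
})

test_that("the panel is the exact overlap of DNB members and VIP selection", {
  p <- build_panel(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(p$proteins, c("B", "C"))
  expect_warning(e <- build_panel(c("A"), c("B")), "disjoint")
  expect_length(e$proteins, 0)
  expect_error(build_panel(character(), "B"), "non-empty")
})

test_that("detection is invariant to protein labelling and scales with SD", {
  sim <- sim_longitudinal_npx(n_patients = 30, n_proteins = 40, n_planted = 6,
                              seed = 12)
  r1 <- dnb_indices(sim$truth$planted, sim$npx, n_perm = 0)
  # relabelling proteins leaves every index unchanged
  m2 <- sim$npx
  rownames(m2$values) <- paste0("X", rownames(m2$values))
  r2 <- dnb_indices(paste0("X", sim$truth$planted), m2, n_perm = 0)
  expect_equal(r2$ci, r1$ci, tolerance = 1e-12)
  # doubling every value doubles sd_avg (and CI), correlations unchanged
  m3 <- sim$npx
  m3$values <- m3$values * 2
  r3 <- dnb_indices(sim$truth$planted, m3, n_perm = 0)
  expect_equal(r3$sd_avg, 2 * r1$sd_avg, tolerance = 1e-10)
  expect_equal(r3$ppc_in, r1$ppc_in, tolerance = 1e-10)
  expect_equal(r3$ci, 2 * r1$ci, tolerance = 1e-8)
})

test_that("end-to-end detection finds the planted cluster", {
  sim <- sim_longitudinal_npx(seed = 31)
  det <- suppressWarnings(dnb_detect(sim$npx, n_perm = 200, seed = 31))
  # most of the planted cluster, with almost no background contamination
  expect_gte(length(intersect(det$members, sim$truth$planted)) / 12, 0.7)
  expect_lte(length(setdiff(det$members, sim$truth$planted)) /
               length(det$members), 0.1)
  # the winning cluster's CI dominates every other cluster's
  other <- setdiff(names(det$reports), det$winner$cluster_id)
  for (nm in other) expect_gt(det$winner$ci, det$reports[[nm]]$ci)
  # wide fluctuation and the PPCi change are detected
  expect_true(det$winner$passes_criteria[["fluctuation"]])
  expect_true(det$winner$passes_criteria[["ppci_change"]])
})
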