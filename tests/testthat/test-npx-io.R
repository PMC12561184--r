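test_that("long NPX tables pivot into a validated matrix", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(sample_id = c("A_D0", "A_D5", "B_D0", "B_D5"),
                    protein_id = c("P1", "P2", "P3"),
                    stringsAsFactors = FALSE)
  df$patient_id <- substr(df$sample_id, 1, 1)
  df$timepoint <- sub("^._", "", df$sample_id)
  df$npx <- seq_len(nrow(df))
  write.csv(df, f, row.names = FALSE)
  m <- read_npx_long(f)
  expect_s3_class(m, "npx_matrix")
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(m$values["P2", "B_D5"], df$npx[df$sample_id == "B_D5" &
                                                df$protein_id == "P2"])

  # duplicated (sample, protein) measurement is rejected naming the pair
  write.csv(rbind(df, df[1, ]), f, row.names = FALSE)
  expect_error(read_npx_long(f), "A_D0.*P1")

  # PD is an accepted label, later mapped by assign_lt
  df2 <- df
  df2$timepoint[df2$sample_id == "B_D5"] <- "PD"
  df2$sample_id[df2$sample_id == "B_D5"] <- "B_PD"
  write.csv(df2, f, row.names = FALSE)
  expect_silent(m2 <- read_npx_long(f))
  expect_true("PD" %in% m2$sample_meta$timepoint)

  # unknown labels are not coerced
  df2$timepoint[df2$sample_id == "A_D0"] <- "D9"
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_npx_long(f), "D9")

  writeLines("", f)
  expect_error(read_npx_long(f))
})

test_that("write/read round trip preserves values, roles and missingness", {
  sim <- sim_longitudinal_npx(n_patients = 6, n_proteins = 8, n_planted = 2,
                              seed = 4)
  m <- sim$npx
  m$values[2, 3] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_npx_long(m, f)
  m2 <- read_npx_long(f)
  expect_equal(m2$values[rownames(m$values), colnames(m$values)], m$values)
  expect_equal(m2$patient_meta[order(m2$patient_meta$patient_id), ],
               m$patient_meta[order(m$patient_meta$patient_id), ],
               ignore_attr = TRUE)
})

test_that("assign_lt picks PD when present, else the last sample", {
  mk <- function(tps) {
    ids <- paste0("A_", tps)
    vals <- matrix(rnorm(2 * length(tps)), 2,
                   dimnames = list(c("P1", "P2"), ids))
    npx_matrix(vals, data.frame(sample_id = ids, patient_id = "A",
                                timepoint = tps))
  }
  full <- assign_lt(mk(c("D0", "D5", "DT", "PD")))
  expect_equal(full$sample_meta$sample_id[full$sample_meta$lt], "A_PD")
  nopd <- assign_lt(mk(c("D0", "D5", "DT")))
  expect_equal(nopd$sample_meta$sample_id[nopd$sample_meta$lt], "A_DT")
  only <- assign_lt(mk("D0"))
  expect_equal(only$sample_meta$sample_id[only$sample_meta$lt], "A_D0")
  # original labels are kept: the LT role is additive
  expect_equal(full$sample_meta$timepoint[full$sample_meta$lt], "PD")
  expect_equal(samples_at(full, "LT"), "A_PD")
})

test_that("npx_matrix validation catches malformed inputs", {
  vals <- matrix(1:4, 2, dimnames = list(c("P1", "P2"), c("s1", "s2")))
  sm <- data.frame(sample_id = c("s1", "s2"), patient_id = "A",
                   timepoint = c("D0", "D0"))
  expect_error(npx_matrix(vals, sm), "patient, timepoint")
  sm$timepoint <- c("D0", "D5")
  expect_error(npx_matrix(vals, sm,
                          data.frame(patient_id = "A", group = "bad")),
               "group")
  rownames(vals) <- c("P1", "P1")
  expect_error(npx_matrix(vals, sm), "unique")
})

test_that("batch adjustment equalizes moments, keeps the reference, idempotent", {
  set.seed(10)
  x <- matrix(rnorm(5 * 40), 5, dimnames = list(paste0("G", 1:5), paste0("s", 1:40)))
  batch <- rep(c("ref", "b2"), each = 20)
  x[, batch == "b2"] <- x[, batch == "b2"] + 5     # pure location shift
  adj <- adjust_batches(x, batch, "ref")
  expect_equal(rowMeans(adj[, batch == "b2"]), rowMeans(adj[, batch == "ref"]))
  expect_identical(adj[, batch == "ref"], x[, batch == "ref"])
  expect_equal(adjust_batches(adj, batch, "ref"), adj)

  # zero-variance gene in a non-reference batch falls back to mean shift
  x2 <- x; x2[1, batch == "b2"] <- 7
  expect_warning(adj2 <- adjust_batches(x2, batch, "ref"), "mean-shift")
  expect_equal(unique(adj2[1, batch == "b2"]), mean(x2[1, batch == "ref"]))
  x3 <- x; x3[1, batch == "ref"] <- 0
  expect_error(adjust_batches(x3, batch, "ref"), "reference")
  expect_error(adjust_batches(x, rep("ref", 40), "ref"), ">= 2 batches")
})

test_that("score ranking is invariant to a gene-uniform shared-scale batch map", {
  set.seed(77)
  genes <- sprintf("G%03d", 1:6)
  model <- structure(list(genes = genes,
                          betas = setNames(rnorm(6), genes)),
                     class = "score_model")
  ref <- matrix(rnorm(6 * 50), 6, dimnames = list(genes, paste0("r", 1:50)))
  shifted <- ref + 2                                # gene-uniform, scale shared
  colnames(shifted) <- paste0("v", 1:50)
  comb <- cbind(ref, shifted)
  adj <- adjust_batches(comb, rep(c("ref", "val"), each = 50), "ref")
  before <- rank(score_subjects(model, shifted))
  after <- rank(score_subjects(model, adj[, colnames(shifted)]))
  expect_identical(before, after)
})

test_that("survival and fraction readers validate their tables", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = c("a", "b"), time = c(5, -1),
                       event = c(1, 0)), f, row.names = FALSE)
  expect_error(read_survival(f), "> 0")
  write.csv(data.frame(subject_id = c("a", "b"), time = c(5, 2),
                       event = c(1, 0), age = c(60, 70)), f, row.names = FALSE)
  sv <- read_survival(f)
  expect_equal(nrow(sv), 2)
  expect_equal(attr(sv, "time_unit"), "months")
  write.csv(data.frame(subject_id = "a", time = 1), f, row.names = FALSE)
  expect_error(read_survival(f), "event")

  # write_report round trip at full precision
  d <- data.frame(gene = c("G1", "G2"), beta = c(pi, exp(1) / 3))
  out <- withr::local_tempdir()
  write_report(list(model = d), out)
  back <- read.csv(file.path(out, "model.csv"))
  expect_identical(back$beta, d$beta)
  expect_true(file.exists(file.path(out, "report_log.txt")))
})

test_that("fraction correlation intersects subjects and warns on mismatch", {
  set.seed(3)
  scores <- setNames(rnorm(20), paste0("s", 1:20))
  fr <- matrix(rnorm(2 * 25), 2,
               dimnames = list(c("CAF", "NK"), paste0("s", 1:25)))
  expect_warning(res <- fraction_correlation(scores, fr), "intersection")
  expect_equal(nrow(res), 2)
  expect_error(fraction_correlation(scores[1:3], fr), "overlap")
})
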