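test_that("compute_delta subtracts aligned matrices and validates inputs", {
  m <- rand_matrix(20, 6)
  expect_equal(compute_delta(m, m)$values, m - m)
  expect_equal(compute_delta(m + 1, m)$values, matrix(1, 20, 6,
                                                      dimnames = dimnames(m)))
  # column order of the control matrix is irrelevant: alignment is by id
  perm <- sample(ncol(m))
  d1 <- compute_delta(m + 2, m)
  d2 <- compute_delta(m + 2, m[, perm])
  expect_identical(d1$values, d2$values)
  expect_false(d1$provenance$quantile_normalized)
  expect_identical(d1$provenance$n_pcs_removed, 0L)
  bad <- m
  rownames(bad)[1] <- "other"
  expect_error(compute_delta(m, bad), "share")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(compute_delta(m_na, m), "non-finite")
})

test_that("quantile normalization maps columns to the mean reference", {
  m <- matrix(c(5, 2, 3, 4, 1, 2), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(4.5, 1.5, 2.5))
  expect_equal(unname(out[, 2]), c(4.5, 1.5, 2.5))
  # single column untouched
  expect_identical(quantile_normalize(m[, 1, drop = FALSE]),
                   m[, 1, drop = FALSE])
  # idempotent; rank-preserving; column-exchangeable
  r <- rand_matrix(50, 8, seed = 3)
  q1 <- quantile_normalize(r)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-9)
  for (j in seq_len(ncol(r))) {
    expect_identical(order(q1[, j]), order(r[, j]))
  }
  perm <- c(3, 1, 2, 8, 7, 4, 5, 6)
  expect_equal(unname(quantile_normalize(r[, perm])), unname(q1[, perm]))
  # columns share one multiset of values
  expect_equal(apply(q1, 2, sort), matrix(rep(sort(q1[, 1]), ncol(q1)),
                                          ncol = ncol(q1),
                                          dimnames = list(NULL, colnames(q1))))
})

test_that("quantile normalization ties take the mean of spanned reference values", {
  m <- matrix(c(1, 1, 5, 2, 3, 4), ncol = 2)
  rownames(m) <- paste0("g", 1:3); colnames(m) <- c("a", "b")
  out <- quantile_normalize(m)
  ref <- unname(rowMeans(apply(m, 2, sort)))   # c(1.5, 2.5, 4.5)
  expect_equal(unname(out[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  r <- rand_matrix(80, 5, seed = 11)
  expect_equal(unname(quantile_normalize(r)),
               unname(limma::normalizeQuantiles(r, ties = TRUE)),
               tolerance = 1e-12)
})

test_that("batch regression removes batch structure and nothing else", {
  m <- rand_matrix(30, 8, seed = 5)
  d <- delta_expression(m)
  batch <- rep(c("b1", "b2"), each = 4)
  # single batch: values unchanged
  one <- regress_out_batch(d, rep("b1", 8))
  expect_equal(one$values, m)
  expect_true(one$provenance$batch_adjusted)
  # pure batch offsets vanish
  off <- delta_expression(matrix(rep(ifelse(batch == "b1", 2, -2), each = 30),
                                 nrow = 30, dimnames = dimnames(m)))
  res <- regress_out_batch(off, batch)
  expect_lt(max(abs(res$values - rowMeans(off$values))), 1e-10)
  # residuals orthogonal to the centered batch indicator
  adj <- regress_out_batch(d, batch)
  ind <- ifelse(batch == "b1", 1, 0) - mean(batch == "b1")
  centered <- adj$values - rowMeans(adj$values)
  expect_lt(max(abs(centered %*% ind)), 1e-8)
  # gene means preserved
  expect_equal(rowMeans(adj$values), rowMeans(m))
  expect_error(regress_out_batch(d, c(rep("b1", 7), "b2")), ">= 2")
})

test_that("sample PCA matches a direct covariance eigendecomposition", {
  m <- rand_matrix(100, 20, seed = 9)
  p <- pca_samples(delta_expression(m))
  # oracle: explicit sample x sample covariance of the gene-centered matrix
  xc <- m - rowMeans(m)
  ev <- eigen(crossprod(xc) / (nrow(m) - 1), symmetric = TRUE)
  ve_oracle <- ev$values / sum(ev$values)
  expect_equal(p$variance_explained[seq_len(19)], ve_oracle[seq_len(19)],
               tolerance = 1e-8)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-9)
  # score columns mutually orthogonal
  g <- crossprod(p$scores[, 1:10])
  expect_lt(max(abs(g - diag(diag(g)))) / max(diag(g)), 1e-6)
})

test_that("rank-1 input concentrates all variance on the first component", {
  u <- c(1, 2, 3, 4, 5)
  v <- c(2, -1, 0.5, 1)
  m <- outer(u, v)
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:4))
  p <- pca_samples(delta_expression(m))
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-12)
  expect_lt(max(p$variance_explained[-1]), 1e-12)
  expect_error(pca_samples(delta_expression(m * 0 + 1)), "zero-variance")
})

test_that("the 0.5 percent rule counts leading informative components", {
  expect_identical(select_n_pcs(c(0.10, 0.02, 0.004, 0.003)), 2L)
  expect_identical(select_n_pcs(rep(1 / 30, 30)), 25L)  # capped at 25
  expect_identical(select_n_pcs(c(0.004, 0.003)), 0L)
  expect_identical(select_n_pcs(c(0.9, 0.1), cap = 1), 1L)
})

test_that("remove_pcs regresses out score columns gene by gene", {
  m <- rand_matrix(60, 12, seed = 13)
  d <- delta_expression(m)
  p <- pca_samples(d)
  # k = 0: quantile normalization only
  expect_equal(remove_pcs(d, p, 0)$values, quantile_normalize(m))
  # rank-1 input, k = 1: residuals vanish before renormalization
  r1 <- outer(seq_len(60), c(seq_len(11), 2.5))
  dimnames(r1) <- dimnames(m)
  dr1 <- delta_expression(r1)
  res1 <- remove_pcs(dr1, pca_samples(dr1), 1, renormalize = FALSE)
  expect_lt(max(abs(res1$values)), 1e-8)
  # raw residuals orthogonal to score columns 1..3, per gene
  res3 <- remove_pcs(d, p, 3, renormalize = FALSE)
  expect_lt(max(abs(res3$values %*% p$scores[, 1:3])), 1e-8)
  expect_identical(res3$provenance$n_pcs_removed, 3L)
  expect_true(remove_pcs(d, p, 2)$provenance$quantile_normalized)
  expect_error(remove_pcs(d, p, -1), "non-negative")
  expect_error(remove_pcs(d, p, 99), "available")
})

test_that("the progressive sweep emits one dataset per correction depth", {
  m <- rand_matrix(80, 30, seed = 17)
  d <- delta_expression(m)
  sweep <- pc_correction_sweep(d, 10)
  expect_length(sweep, 10)
  expect_identical(purrr::map_int(sweep, ~ .x$provenance$n_pcs_removed), 1:10)
  # identity and order of genes/samples preserved throughout
  for (ds in sweep) {
    expect_identical(rownames(ds$values), rownames(m))
    expect_identical(colnames(ds$values), colnames(m))
  }
  p <- pca_samples(d)
  expect_equal(sweep[[1]]$values, remove_pcs(d, p, 1)$values)
  expect_error(pc_correction_sweep(d, 99), "exceeds")
})

test_that("PC removal drains the dominant confounder energy", {
  # on confounded data the leading shares collapse below the pre-correction
  # k-th share once the k confounder proxies are regressed out
  prep <- prepared_study(simulation_config(n_genes = 300L, n_signature = 10L,
                                           n_background_samples = 20L,
                                           seed = 19L))
  k <- 3
  ve_before <- prep$pca$variance_explained
  expect_gt(ve_before[k], 0.1)  # confounders dominate before correction
  ve_after <- pca_samples(remove_pcs(prep$delta, prep$pca, k))$variance_explained
  expect_true(all(ve_after[seq_len(k)] < ve_before[k]))
})

test_that("PC-covariate diagnostics flag real and null associations correctly", {
  m <- rand_matrix(100, 40, seed = 21)
  p <- pca_samples(delta_expression(m))
  ph <- tibble::tibble(sample_id = colnames(m),
                       age = p$scores[, 1],        # numeric = PC1 exactly
                       sex = rep(c("M", "F"), 20),
                       smoker = "no")              # constant
  diag <- pc_covariate_diagnostics(p, ph, n_pcs = 5,
                                   covariates = c("age", "sex", "smoker"))
  pc1_age <- diag[diag$pc == 1 & diag$covariate == "age", ]
  expect_equal(abs(pc1_age$statistic), 1)
  expect_identical(diag$note[diag$covariate == "smoker"][1],
                   "constant covariate")
  expect_true(all(is.na(diag$p_value[diag$covariate == "smoker"])))
  expect_identical(nrow(diag), 15L)
})

test_that("null covariates reach nominal false-positive rates", {
  m <- rand_matrix(150, 40, seed = 23)
  p <- pca_samples(delta_expression(m))
  hits <- withr::with_seed(77, {
    vapply(1:200, function(i) {
      ph <- tibble::tibble(sample_id = colnames(m), x = rnorm(40))
      dg <- pc_covariate_diagnostics(p, ph, n_pcs = 20, covariates = "x")
      sum(dg$p_value < 0.05)
    }, numeric(1))
  })
  rate <- sum(hits) / (200 * 20)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("removing the confounder PCs erases covariate associations", {
  cfg <- simulation_config(n_genes = 300L, n_signature = 1L, effect_size = 0,
                           n_confounders = 3L, covariate_confounder_corr = 0.9,
                           batch_effect_sd = 0, seed = 31L)
  st <- simulate_study(cfg)
  d <- quantile_normalize(compute_delta(st$statin, st$control))
  p <- pca_samples(d)
  dg_before <- pc_covariate_diagnostics(p, st$cohort, n_pcs = 3,
                                        covariates = "age")
  expect_gt(max(abs(dg_before$statistic)), 0.5)  # confounder proxy visible
  corrected <- remove_pcs(d, p, 3)
  p_after <- pca_samples(corrected)
  dg <- pc_covariate_diagnostics(p_after, st$cohort, n_pcs = 3,
                                 covariates = "age")
  expect_true(all(abs(dg$statistic) < 0.2))
})
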