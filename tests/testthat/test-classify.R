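test_that("the RBF classifier separates well-separated classes", {
  withr::with_seed(69, {
    x <- matrix(c(rnorm(10, -10, 0.1), rnorm(10, 10, 0.1)), ncol = 1)
    x <- cbind(x, x[, 1] + rnorm(20, sd = 0.1))
  })
  rownames(x) <- sprintf("s%02d", 1:20)
  labs <- rep(c("low", "high"), each = 10)
  clf <- train_rbf_classifier(x, labs)
  scores <- predict(clf, x)
  expect_equal(auc(scores, labs), 1)
  expect_true(all(scores[labs == "high"] > scores[labs == "low"]))
  expect_error(train_rbf_classifier(x, rep("high", 20)), "two classes")
  expect_warning(train_rbf_classifier(cbind(x, 0), labs), "zero-variance")
})

test_that("duplicating separable training samples leaves scores unchanged", {
  withr::with_seed(71, {
    x <- rbind(matrix(rnorm(40, -5), ncol = 4), matrix(rnorm(40, 5), ncol = 4))
    probe <- matrix(rnorm(80), ncol = 4)
  })
  rownames(x) <- sprintf("s%02d", 1:20)
  labs <- rep(c("low", "high"), each = 10)
  clf1 <- train_rbf_classifier(x, labs, sigma = 0.05)
  x2 <- rbind(x, x)
  rownames(x2) <- sprintf("s%02d", 1:40)
  clf2 <- train_rbf_classifier(x2, c(labs, labs), sigma = 0.05)
  expect_equal(predict(clf1, probe), predict(clf2, probe), tolerance = 1e-6)
})

test_that("shuffled labels give chance-level performance", {
  withr::with_seed(73, {
    x <- matrix(rnorm(26 * 10), nrow = 26,
                dimnames = list(sprintf("s%02d", 1:26), NULL))
    labs <- sample(rep(c("high", "low"), c(12, 14)))
  })
  ev <- repeated_split_eval(x, labs, n_repeats = 400, seed = 5)
  expect_gt(ev$auc, 0.35)
  expect_lt(ev$auc, 0.65)
})

test_that("the ROC curve enumerates thresholds with joint tie steps", {
  r <- roc_curve(c(0.9, 0.8, 0.7, 0.6), c("high", "high", "low", "low"))
  expect_equal(r$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(r$tpr, c(0, 0.5, 1, 1, 1))
  # all scores tied: one block from (0,0) to (1,1)
  r2 <- roc_curve(rep(1, 6), rep(c("high", "low"), 3))
  expect_equal(r2$fpr, c(0, 1))
  expect_equal(r2$tpr, c(0, 1))
  # curve coordinates are non-decreasing and bracketed
  withr::with_seed(79, {
    s <- round(rnorm(60), 1)  # forces ties
    l <- sample(c("high", "low"), 60, replace = TRUE)
  })
  r3 <- roc_curve(s, l)
  expect_true(all(diff(r3$fpr) >= 0) && all(diff(r3$tpr) >= 0))
  expect_equal(unlist(r3[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r3[nrow(r3), ]), c(fpr = 1, tpr = 1))
  # oracle: brute-force threshold enumeration
  thr <- sort(unique(s), decreasing = TRUE)
  pts <- t(sapply(thr, function(t0) {
    c(sum(s >= t0 & l == "low") / sum(l == "low"),
      sum(s >= t0 & l == "high") / sum(l == "high"))
  }))
  expect_equal(unname(as.matrix(r3[-1, ])), unname(pts), tolerance = 1e-12)
  expect_error(roc_curve(1:3, rep("high", 3)), "both classes")
})

test_that("AUC equals pair counting, trapezoids, and external references", {
  expect_equal(auc(c(4, 3, 2, 1), c("high", "high", "low", "low")), 1)
  expect_equal(auc(c(0.9, 0.4, 0.7, 0.6), c("high", "high", "low", "low")), 0.5)
  expect_equal(auc(rep(2, 8), rep(c("high", "low"), 4)), 0.5)
  brute_auc <- function(s, l) {
    pos <- s[l == "high"]; neg <- s[l == "low"]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  trap_auc <- function(r) sum(diff(r$fpr) * (utils::head(r$tpr, -1) +
                                               utils::tail(r$tpr, -1)) / 2)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(10:200, 1)
      s <- round(rnorm(n), 1)
      l <- sample(c("high", "low"), n, replace = TRUE)
      if (length(unique(l)) < 2) l[1:2] <- c("high", "low")
    })
    a <- auc(s, l)
    expect_equal(a, brute_auc(s, l), tolerance = 1e-12)
    expect_equal(a, trap_auc(roc_curve(s, l)), tolerance = 1e-9)
    # complement and monotone-transform identities
    expect_equal(auc(-s, l), 1 - a + 0.5 * 0, tolerance = 1e-12)
    expect_equal(auc(exp(s / 2), l), a, tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a seeded case", {
  skip_if_not_installed("pROC")
  withr::with_seed(83, {
    s <- rnorm(100)
    l <- sample(c("high", "low"), 100, replace = TRUE)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, levels = c("low", "high"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc(s, l), ref, tolerance = 1e-12)
})

test_that("repeated splits are seeded, stratified and pooled", {
  withr::with_seed(89, {
    x <- rbind(matrix(rnorm(12 * 5, 5), ncol = 5),
               matrix(rnorm(14 * 5, -5), ncol = 5))
  })
  rownames(x) <- sprintf("s%02d", 1:26)
  labs <- rep(c("high", "low"), c(12, 14))
  e1 <- repeated_split_eval(x, labs, n_repeats = 50, seed = 4)
  e2 <- repeated_split_eval(x, labs, n_repeats = 50, seed = 4)
  expect_identical(e1$pooled_scores, e2$pooled_scores)
  expect_gt(e1$auc, 0.95)       # strongly separable features
  expect_equal(e1$n_repeats, 50L)
  expect_warning(repeated_split_eval(x[9:16, ], labs[9:16], n_repeats = 5,
                                     n_folds = 10, seed = 1),
                 "relaxed")
  expect_error(repeated_split_eval(x, labs, n_repeats = 0), "n_repeats")
})

test_that("cross-ancestry AUC is non-decreasing in the planted effect", {
  for (seed in 1:3) {
    aucs <- vapply(c(0, 0.5, 1, 2), function(es) {
      prep <- prepared_study(simulation_config(
        n_genes = 400L, n_signature = 30L, effect_size = es,
        n_background_samples = 10L, seed = seed))
      ds <- remove_pcs(prep$delta, prep$pca, 3)
      sig <- compute_signature(ds, prep$disc)
      ids <- names(prep$val)[prep$val %in% c("high", "low")]
      feats <- t(ds$values[top_k_genes(sig, 50), ids])
      repeated_split_eval(feats, prep$val[ids], n_repeats = 150,
                          seed = seed)$auc
    }, numeric(1))
    expect_true(all(diff(aucs) >= -0.03))
  }
})

test_that("the PC sweep evaluates every correction depth in order", {
  prep <- prepared_study(simulation_config(n_genes = 250L, n_signature = 20L,
                                           n_background_samples = 6L,
                                           seed = 97L))
  datasets <- pc_correction_sweep(prep$delta, 5)
  sw <- pc_sweep_eval(datasets, prep$disc, prep$val, n_top_genes = 40,
                      n_repeats = 25, seed = 2)
  expect_length(sw$evals, 5)
  expect_identical(sw$summary$n_pcs, 1:5)
  expect_identical(purrr::map_int(sw$evals, "n_pcs"), 1:5)
  expect_true(all(sw$summary$auc >= 0 & sw$summary$auc <= 1))
  expect_identical(sw$best_k, sw$summary$n_pcs[which.max(sw$summary$auc)])
  expect_s3_class(tidy(sw), "tbl_df")
  expect_identical(glance(sw)$best_k, sw$best_k)
})

test_that("the optimal correction depth is at or beyond the confounder count", {
  for (seed in 4:6) {
    prep <- prepared_study(simulation_config(n_genes = 400L,
                                             n_signature = 40L,
                                             n_background_samples = 10L,
                                             seed = seed))
    datasets <- pc_correction_sweep(prep$delta, 6)
    sw <- pc_sweep_eval(datasets, prep$disc, prep$val, n_top_genes = 50,
                        n_repeats = 60, seed = seed)
    best_auc <- max(sw$summary$auc)
    best_deep <- max(sw$summary$auc[sw$summary$n_pcs >= 3])
    expect_gte(best_deep, best_auc - 0.03)
  }
})

test_that("the gene-count sweep sizes panels and reports the best", {
  prep <- prepared_study(simulation_config(n_genes = 250L, n_signature = 20L,
                                           n_background_samples = 6L,
                                           seed = 103L))
  ds <- remove_pcs(prep$delta, prep$pca, 3)
  grid <- seq(10, 50, by = 10)
  gs <- gene_count_sweep(ds, prep$disc, prep$val, n_grid = grid,
                         n_repeats = 20, seed = 9)
  expect_identical(gs$summary$n_genes, as.integer(grid))
  expect_length(gs$evals, length(grid))
  expect_identical(gs$best_n,
                   gs$summary$n_genes[which.max(gs$summary$auc)])
  single <- gene_count_sweep(ds, prep$disc, prep$val, n_grid = 25,
                             n_repeats = 10, seed = 9)
  expect_identical(single$best_n, 25L)
  expect_error(gene_count_sweep(ds, prep$disc, prep$val, n_grid = integer(0)),
               "non-empty")
  expect_error(gene_count_sweep(ds, prep$disc, prep$val, n_grid = 9999),
               "exceeds")
})
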