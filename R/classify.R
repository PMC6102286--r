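#' Train a radial-basis-kernel classifier of responder class
#'
#' Fits a C-support-vector machine with a Gaussian (radial basis function)
#' kernel on a samples x genes feature matrix.  The kernel width is set
#' deterministically by the median heuristic (inverse of the median pairwise
#' squared Euclidean distance between training samples) unless supplied, and
#' the cost parameter defaults to 1.  Decision scores are oriented so that
#' larger values mean more "high responder".
#'
#' @param features Numeric samples x genes matrix.
#' @param labels Two-class per-sample labels (`"high"` / `"low"`, or any two
#'   levels with `positive` naming the class scores should increase with).
#' @param cost SVM cost parameter.
#' @param sigma RBF inverse-width; `NULL` = median heuristic.
#' @param positive Label of the positive class (default `"high"`, else the
#'   last factor level).
#' @return A list of class `rbf_classifier` with the fitted model, `sigma`,
#'   `cost`, `positive` and a `flip` flag fixing score orientation.
#' @export
train_rbf_classifier <- function(features, labels, cost = 1, sigma = NULL,
                                 positive = NULL) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("non-finite feature values", call. = FALSE)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("training labels must contain exactly two classes",
                             call. = FALSE)
  if (is.null(positive)) positive <- if ("high" %in% cls) "high" else cls[2]
  if (!positive %in% cls) stop("positive class not present in labels", call. = FALSE)
  if (any(apply(features, 2, stats::var) == 0)) {
    warning("zero-variance feature(s) in the training matrix")
  }
  if (is.null(sigma)) sigma <- median_heuristic_sigma(features)
  y <- factor(labels, levels = c(setdiff(cls, positive), positive))
  fit <- with_seed(760613L, kernlab::ksvm(
    x = features, y = y, type = "C-svc", kernel = "rbfdot",
    kpar = list(sigma = sigma), C = cost, scaled = FALSE, prob.model = FALSE
  ))
  dec <- kernlab::predict(fit, features, type = "decision")[, 1]
  flip <- mean(dec[y == positive]) < mean(dec[y != positive])
  structure(list(model = fit, sigma = sigma, cost = cost,
                 positive = positive, flip = flip),
            class = "rbf_classifier")
}

median_heuristic_sigma <- function(features) {
  d2 <- stats::dist(features)^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m == 0) 1 else 1 / m
}

#' Decision scores of a fitted RBF classifier
#'
#' @param object An `rbf_classifier`.
#' @param newdata Samples x genes matrix with the training feature columns.
#' @param ... Unused.
#' @return Numeric decision scores, higher = more like the positive class.
#' @export
predict.rbf_classifier <- function(object, newdata, ...) {
  dec <- kernlab::predict(object$model, as.matrix(newdata),
                          type = "decision")[, 1]
  if (object$flip) -dec else dec
}

#' Repeated stratified-split evaluation, pooled over test folds
#'
#' Each repeat draws a fresh class-stratified random partition of the samples
#' into `n_folds` subsets; one subset is held out as the test set and the
#' others train an RBF classifier whose decision scores on the held-out
#' samples are appended to a pool.  After `n_repeats` test folds the pooled
#' scores and labels are summarised by an ROC curve and its AUC.
#'
#' @param features Samples x genes matrix.
#' @param labels Two-class labels aligned with the rows.
#' @param n_repeats Number of test folds pooled.
#' @param n_folds Number of partitions per repeat (9:1 train:test at 10).
#' @param seed RNG seed for the partitions.
#' @param cost,sigma Passed to [train_rbf_classifier()].
#' @param positive Positive class (see [train_rbf_classifier()]).
#' @return A list of class `classifier_eval`: `pooled_scores`,
#'   `pooled_labels`, `roc_points`, `auc`, `n_repeats`, `n_folds`,
#'   `n_genes`, `n_pcs` (`NA` here; filled by the sweeps), `seed`.
#' @export
repeated_split_eval <- function(features, labels, n_repeats = 5000L,
                                n_folds = 10L, seed = 1L, cost = 1,
                                sigma = NULL, positive = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("labels must contain exactly two classes", call. = FALSE)
  stratified <- all(table(labels) >= n_folds)
  if (!stratified) {
    warning("a class has fewer members than n_folds; ",
            "stratification relaxed to a plain random partition")
  }
  if (is.null(sigma)) sigma <- median_heuristic_sigma(features)
  n <- nrow(features)
  pooled_scores <- vector("list", n_repeats)
  pooled_labels <- vector("list", n_repeats)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      repeat {
        fold <- integer(n)
        if (stratified) {
          for (cl in cls) {
            idx <- which(labels == cl)
            fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
          }
        } else {
          fold <- sample(rep_len(seq_len(n_folds), n))
        }
        test <- fold == 1L
        if (any(test) && length(unique(labels[!test])) == 2) break
      }
      clf <- train_rbf_classifier(features[!test, , drop = FALSE],
                                  labels[!test], cost = cost, sigma = sigma,
                                  positive = positive)
      pooled_scores[[r]] <- predict(clf, features[test, , drop = FALSE])
      pooled_labels[[r]] <- labels[test]
    }
  })
  scores <- unlist(pooled_scores)
  labs <- unlist(pooled_labels)
  pos <- if (is.null(positive)) {
    if ("high" %in% cls) "high" else cls[2]
  } else positive
  structure(
    list(pooled_scores = scores, pooled_labels = labs,
         roc_points = roc_curve(scores, labs, positive = pos),
         auc = auc(scores, labs, positive = pos),
         n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
         n_genes = ncol(features), n_pcs = NA_integer_,
         positive = pos, seed = as.integer(seed)),
    class = "classifier_eval"
  )
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf(
    "<classifier_eval> AUC = %.3f (%d genes%s; %d pooled test folds)\n",
    x$auc, x$n_genes,
    if (is.na(x$n_pcs)) "" else sprintf(", %d PCs removed", x$n_pcs),
    x$n_repeats))
  invisible(x)
}

#' ROC curve by descending score threshold
#'
#' Sweeps the classification threshold from high to low and records the
#' (false-positive-rate, true-positive-rate) pair after each distinct score
#' value; tied scores advance both coordinates jointly.  The curve starts at
#' (0, 0) and ends at (1, 1).
#'
#' @param scores Numeric decision scores, higher = more positive.
#' @param labels Two-class labels.
#' @param positive Positive-class label (default `"high"`, else last level).
#' @return A tibble of ordered `fpr`, `tpr` points.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("both classes must be present", call. = FALSE)
  if (is.null(positive)) positive <- if ("high" %in% cls) "high" else cls[2]
  pos <- labels == positive
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)  # end of each tie block
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  tibble::tibble(fpr = c(0, fp / sum(!pos)), tpr = c(0, tp / sum(pos)))
}

#' Area under the ROC curve
#'
#' The probability that a random positive sample outscores a random negative
#' one, ties counting one half; identical to the trapezoidal area under
#' [roc_curve()].  Computed from the rank statistic.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("both classes must be present", call. = FALSE)
  if (is.null(positive)) positive <- if ("high" %in% cls) "high" else cls[2]
  pos <- labels == positive
  n_p <- sum(pos)
  n_n <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n_p * (n_p + 1) / 2) / (n_p * n_n)
}

#' Cross-ancestry AUC across the PC-correction sweep
#'
#' For each corrected dataset: identify signature genes on the discovery
#' (EA) tails, keep the top `n_top_genes` by `|d|`, restrict the validation
#' (AA) samples to those gene features, and evaluate an RBF classifier of the
#' AA responder classes by [repeated_split_eval()].
#'
#' @param corrected_datasets List of `delta_expression` objects from
#'   [pc_correction_sweep()] (any list of corrected datasets works).
#' @param discovery_labels,validation_labels Responder classes named by
#'   sample id (`"high"`/`"low"`, others ignored) for the discovery and
#'   validation cohorts.
#' @param n_top_genes Signature panel size per dataset.
#' @param n_repeats,n_folds,cost,sigma Passed to [repeated_split_eval()].
#' @param s0_method Fudge-factor method for the per-dataset signatures.
#' @param train_on_discovery If `TRUE`, train one classifier on the discovery
#'   tails and score the validation samples once instead of the repeated
#'   within-validation splits.
#' @param seed Base seed; dataset `k` uses `seed + k`.
#' @return A list of class `pc_sweep_eval`: `evals` (one `classifier_eval`
#'   per dataset, in order), `summary` tibble (`n_pcs`, `n_genes`, `auc`),
#'   `best_k` (arg-max AUC, ties to the smallest `k`).
#' @export
pc_sweep_eval <- function(corrected_datasets, discovery_labels,
                          validation_labels, n_top_genes = 100L,
                          n_repeats = 5000L, n_folds = 10L, seed = 1L,
                          cost = 1, sigma = NULL, s0_method = "cv_min",
                          train_on_discovery = FALSE) {
  stopifnot(length(corrected_datasets) >= 1)
  evals <- purrr::imap(corrected_datasets, function(ds, k) {
    ev <- panel_eval(ds, discovery_labels, validation_labels,
                     n_top_genes = n_top_genes, n_repeats = n_repeats,
                     n_folds = n_folds, seed = seed + as.integer(k),
                     cost = cost, sigma = sigma, s0_method = s0_method,
                     train_on_discovery = train_on_discovery)
    ev$n_pcs <- as_delta(ds)$provenance$n_pcs_removed
    ev
  })
  aucs <- purrr::map_dbl(evals, "auc")
  structure(
    list(evals = evals,
         summary = tibble::tibble(
           n_pcs = purrr::map_int(evals, "n_pcs"),
           n_genes = as.integer(n_top_genes),
           auc = aucs),
         best_k = purrr::map_int(evals, "n_pcs")[which.max(aucs)],
         seed = as.integer(seed)),
    class = "pc_sweep_eval"
  )
}

# shared core of the two sweeps: signature on discovery tails -> top-n panel
# -> classifier evaluation on the validation cohort
panel_eval <- function(dataset, discovery_labels, validation_labels,
                       n_top_genes, n_repeats, n_folds, seed, cost, sigma,
                       s0_method, train_on_discovery = FALSE,
                       signature = NULL) {
  ds <- as_delta(dataset)
  if (is.null(signature)) {
    signature <- compute_signature(ds, discovery_labels, s0_method = s0_method)
  }
  panel <- top_k_genes(signature, n_top_genes)
  val_ids <- names(validation_labels)[validation_labels %in% c("high", "low")]
  missing <- setdiff(val_ids, colnames(ds$values))
  if (length(missing)) {
    stop("validation samples absent from dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  features <- t(ds$values[panel, val_ids, drop = FALSE])
  labs <- validation_labels[val_ids]
  if (train_on_discovery) {
    disc_ids <- names(discovery_labels)[discovery_labels %in% c("high", "low")]
    clf <- train_rbf_classifier(t(ds$values[panel, disc_ids, drop = FALSE]),
                                discovery_labels[disc_ids], cost = cost,
                                sigma = sigma)
    scores <- predict(clf, features)
    structure(
      list(pooled_scores = scores, pooled_labels = unname(labs),
           roc_points = roc_curve(scores, labs, positive = "high"),
           auc = auc(scores, labs, positive = "high"),
           n_repeats = 1L, n_folds = NA_integer_,
           n_genes = length(panel), n_pcs = NA_integer_,
           positive = "high", seed = as.integer(seed)),
      class = "classifier_eval")
  } else {
    ev <- repeated_split_eval(features, labs, n_repeats = n_repeats,
                              n_folds = n_folds, seed = seed, cost = cost,
                              sigma = sigma, positive = "high")
    ev
  }
}

#' Refine the signature-panel size at a fixed correction depth
#'
#' Computes the discovery signature once on `dataset`, then evaluates nested
#' top-`n` panels for every `n` in `n_grid` via [repeated_split_eval()] on the
#' validation cohort, reporting the `n` with maximal AUC (ties to the
#' smallest `n`).
#'
#' @inheritParams pc_sweep_eval
#' @param dataset One corrected `delta_expression`.
#' @param n_grid Integer vector of panel sizes (e.g. `70:90`).
#' @return A list of class `gene_count_sweep`: `evals`, `summary`
#'   (`n_genes`, `auc`), `best_n`, and the discovery `signature`.
#' @export
gene_count_sweep <- function(dataset, discovery_labels, validation_labels,
                             n_grid = 70:90, n_repeats = 5000L, n_folds = 10L,
                             seed = 1L, cost = 1, sigma = NULL,
                             s0_method = "cv_min",
                             train_on_discovery = FALSE) {
  if (length(n_grid) == 0) stop("n_grid must be non-empty", call. = FALSE)
  ds <- as_delta(dataset)
  if (max(n_grid) > nrow(ds$values)) {
    stop("n_grid exceeds the number of genes", call. = FALSE)
  }
  signature <- compute_signature(ds, discovery_labels, s0_method = s0_method)
  evals <- purrr::imap(as.list(as.integer(n_grid)), function(n, i) {
    ev <- panel_eval(ds, discovery_labels, validation_labels,
                     n_top_genes = n, n_repeats = n_repeats,
                     n_folds = n_folds, seed = seed + as.integer(i),
                     cost = cost, sigma = sigma, s0_method = s0_method,
                     train_on_discovery = train_on_discovery,
                     signature = signature)
    ev$n_pcs <- ds$provenance$n_pcs_removed
    ev
  })
  aucs <- purrr::map_dbl(evals, "auc")
  structure(
    list(evals = evals,
         summary = tibble::tibble(n_genes = as.integer(n_grid), auc = aucs),
         best_n = as.integer(n_grid)[which.max(aucs)],
         signature = signature, seed = as.integer(seed)),
    class = "gene_count_sweep"
  )
}

#' @export
print.pc_sweep_eval <- function(x, ...) {
  cat(sprintf("<pc_sweep_eval> %d datasets; best k = %d (AUC = %.3f)\n",
              nrow(x$summary), x$best_k, max(x$summary$auc)))
  invisible(x)
}

#' @export
print.gene_count_sweep <- function(x, ...) {
  cat(sprintf("<gene_count_sweep> %d panel sizes; best n = %d (AUC = %.3f)\n",
              nrow(x$summary), x$best_n, max(x$summary$auc)))
  invisible(x)
}
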