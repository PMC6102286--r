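#' Statin-minus-control delta expression
#'
#' Subtracts the control-treated from the statin-treated variance-stabilized
#' matrix, after aligning the control matrix to the statin matrix's gene and
#' sample order.  Both matrices must carry identical gene and sample id sets
#' (any order).
#'
#' @param statin,control Numeric genes x samples matrices with gene ids as
#'   rownames and sample ids as colnames.
#' @return A [delta_expression()] in the statin matrix's order, provenance
#'   flags unset.
#' @export
compute_delta <- function(statin, control) {
  stopifnot(is.matrix(statin), is.matrix(control))
  if (!setequal(rownames(statin), rownames(control)) ||
      !setequal(colnames(statin), colnames(control))) {
    stop("statin and control matrices must share gene and sample id sets",
         call. = FALSE)
  }
  if (any(!is.finite(statin)) || any(!is.finite(control))) {
    stop("input matrices contain non-finite entries", call. = FALSE)
  }
  control <- control[rownames(statin), colnames(statin), drop = FALSE]
  delta_expression(statin - control)
}

#' Quantile normalization to the across-column mean distribution
#'
#' Forces every sample (column) onto one reference distribution: the mean of
#' the column-wise order statistics.  Within a column, tied values receive the
#' mean of the reference values their ranks span, so each column's rank order
#' is preserved and (absent ties) all columns share exactly one multiset of
#' values.
#'
#' @param x A numeric matrix (genes x samples) or a [delta_expression()].
#' @return Same type as the input; for a `delta_expression` the
#'   `quantile_normalized` provenance flag is set.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "delta_expression")) {
    out <- x
    out$values <- qn_matrix(x$values)
    out$provenance$quantile_normalized <- TRUE
    return(out)
  }
  qn_matrix(x)
}

qn_matrix <- function(x) {
  if (!is.matrix(x) || length(x) == 0) {
    stop("quantile normalization needs a non-empty numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite values in matrix", call. = FALSE)
  if (ncol(x) == 1) return(x)
  ref <- rowMeans(apply(x, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(x, 2, function(col) {
    rmin <- rank(col, ties.method = "min")
    rmax <- rank(col, ties.method = "max")
    (cs[rmax + 1L] - cs[rmin]) / (rmax - rmin + 1L)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Regress experiment batch out of each gene's delta values
#'
#' Per gene, replaces the sample vector by the residuals of a least-squares
#' regression on the batch factor, re-centered to the gene's original mean.
#' With a single batch level the values are returned unchanged.
#'
#' @param delta A [delta_expression()].
#' @param batch Per-sample batch factor (length = number of samples), or the
#'   name is taken from `names(batch)` to align by sample id.
#' @return A `delta_expression` with `batch_adjusted = TRUE`.
#' @export
regress_out_batch <- function(delta, batch) {
  delta <- as_delta(delta)
  x <- delta$values
  if (!is.null(names(batch))) {
    if (!all(colnames(x) %in% names(batch))) {
      stop("batch is missing samples: ",
           paste(setdiff(colnames(x), names(batch)), collapse = ", "),
           call. = FALSE)
    }
    batch <- batch[colnames(x)]
  }
  if (length(batch) != ncol(x)) {
    stop("batch must be defined for every sample", call. = FALSE)
  }
  batch <- factor(batch)
  if (any(table(batch) < 2)) {
    stop("every batch level needs >= 2 samples (singular fit otherwise)",
         call. = FALSE)
  }
  if (nlevels(batch) > 1) {
    qrm <- qr(stats::model.matrix(~batch))
    res <- t(qr.resid(qrm, t(x)))
    x <- res + rowMeans(delta$values)
    dimnames(x) <- dimnames(delta$values)
  }
  delta$values <- x
  delta$provenance$batch_adjusted <- TRUE
  delta
}

#' Principal components of the between-sample covariance
#'
#' Gene-centers the delta matrix and eigendecomposes the sample x sample
#' covariance (equivalently, an SVD of the centered matrix): the score columns
#' are the sample-space principal components, ordered by the proportion of
#' variance they explain.  These PCs serve as proxies for unmeasured
#' confounders.
#'
#' @param delta A [delta_expression()] (or genes x samples matrix) with at
#'   least 2 genes and 2 samples.
#' @return A list of class `pca_result`: `scores` (samples x components, rows
#'   named by sample id) and `variance_explained` (proportions, one per
#'   component, non-increasing and summing to 1).
#' @export
pca_samples <- function(delta) {
  delta <- as_delta(delta)
  x <- delta$values
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  }
  tot <- sum((x - rowMeans(x))^2)
  if (tot < .Machine$double.eps) stop("zero-variance matrix", call. = FALSE)
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, variance_explained = ve), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples x %d components; leading shares: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of PCs to correct, by the 0.5 percent rule
#'
#' Counts leading components while each still explains at least `threshold`
#' of the variance, capped at `cap`: the largest `k <= cap` such that
#' components `1..k` all explain at least `threshold`.
#'
#' @param variance_explained Non-increasing proportions from [pca_samples()]
#'   (a `pca_result` is also accepted).
#' @param threshold Minimum proportion of variance per retained PC.
#' @param cap Maximum number of PCs.
#' @return Integer count (0 if the first PC is already below threshold).
#' @export
select_n_pcs <- function(variance_explained, threshold = 0.005, cap = 25L) {
  if (inherits(variance_explained, "pca_result")) {
    variance_explained <- variance_explained$variance_explained
  }
  ok <- variance_explained >= threshold
  first_bad <- match(FALSE, ok, nomatch = length(ok) + 1L)
  min(as.integer(cap), first_bad - 1L)
}

#' Regress the leading k PCs out of every gene
#'
#' Per gene, takes the residual of a least-squares regression of the gene's
#' sample vector on score columns `1..k` (with intercept), then quantile
#' normalizes the residual matrix.  With `k = 0` the input is only quantile
#' normalized.
#'
#' @param delta A [delta_expression()].
#' @param pca A `pca_result` for the same samples.
#' @param k Number of leading components to remove.
#' @param renormalize Quantile normalize the residuals (the default, matching
#'   the pipeline); `FALSE` returns the raw regression residuals.
#' @return A `delta_expression` with `n_pcs_removed = k` and
#'   `quantile_normalized = TRUE` (unless `renormalize = FALSE`).
#' @export
remove_pcs <- function(delta, pca, k, renormalize = TRUE) {
  delta <- as_delta(delta)
  stopifnot(inherits(pca, "pca_result"))
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  if (k > ncol(pca$scores)) {
    stop("k exceeds the number of available components", call. = FALSE)
  }
  x <- delta$values
  if (k > 0) {
    s <- pca$scores[colnames(x), seq_len(k), drop = FALSE]
    qrm <- qr(cbind(1, s))
    x <- t(qr.resid(qrm, t(x)))
    dimnames(x) <- dimnames(delta$values)
  }
  if (renormalize) {
    delta$values <- qn_matrix(x)
    delta$provenance$quantile_normalized <- TRUE
  } else {
    delta$values <- x
  }
  delta$provenance$n_pcs_removed <- as.integer(k)
  delta
}

#' Progressive PC-correction sweep
#'
#' Produces the family of corrected datasets used for model selection: for
#' each `k = 1..k_max`, the input with PCs `1..k` regressed out (all against
#' the one PCA of the input, or re-estimated per step if
#' `recompute_pca = TRUE`) and re-quantile-normalized.
#'
#' @param delta A [delta_expression()] (already quantile normalized and
#'   batch adjusted, typically).
#' @param k_max Largest correction depth; must not exceed the number of
#'   available components.
#' @param recompute_pca If `TRUE`, re-estimate the PCA on each step's input
#'   residuals instead of reusing the initial PCA.
#' @return A list of `k_max` `delta_expression` objects, in order
#'   `n_pcs_removed = 1..k_max`.
#' @export
pc_correction_sweep <- function(delta, k_max = 25L, recompute_pca = FALSE) {
  delta <- as_delta(delta)
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  pca <- pca_samples(delta)
  if (k_max > ncol(pca$scores)) {
    stop("k_max exceeds the number of available components", call. = FALSE)
  }
  if (!recompute_pca) {
    out <- lapply(seq_len(k_max), function(k) remove_pcs(delta, pca, k))
  } else {
    out <- vector("list", k_max)
    current <- delta
    for (k in seq_len(k_max)) {
      step_pca <- pca_samples(current)
      current <- remove_pcs(current, step_pca, 1L)
      current$provenance$n_pcs_removed <- k
      out[[k]] <- current
    }
  }
  out
}

#' PC-covariate association diagnostics
#'
#' Tests each of the leading PCs against each phenotype covariate: Spearman
#' rank correlation for numeric covariates, a Kruskal-Wallis rank test for
#' categorical ones.  Used to check that confounder proxies fade as the
#' correction depth increases.
#'
#' @param pca A `pca_result` whose score rows are named by sample id.
#' @param phenotypes Phenotype tibble with `sample_id` and the covariates.
#' @param n_pcs How many leading PCs to test.
#' @param covariates Covariate column names (default: age, sex, smoker, batch
#'   where present).
#' @return A tibble with one row per (PC, covariate): `pc`, `covariate`,
#'   `test`, `statistic`, `p_value`, `note` (`"constant covariate"` rows carry
#'   `NA` statistics).
#' @export
pc_covariate_diagnostics <- function(pca, phenotypes, n_pcs = 20L,
                                     covariates = NULL) {
  stopifnot(inherits(pca, "pca_result"), is.data.frame(phenotypes))
  if (is.null(covariates)) {
    covariates <- intersect(c("age", "sex", "smoker", "batch"),
                            names(phenotypes))
  }
  if (!all(phenotypes$sample_id %in% rownames(pca$scores))) {
    stop("phenotype table contains samples absent from the PCA", call. = FALSE)
  }
  scores <- pca$scores[phenotypes$sample_id, , drop = FALSE]
  n_pcs <- min(n_pcs, ncol(scores))
  purrr::map_dfr(seq_len(n_pcs), function(j) {
    purrr::map_dfr(covariates, function(cv) {
      v <- phenotypes[[cv]]
      if (length(unique(v)) < 2) {
        return(tibble::tibble(pc = j, covariate = cv, test = NA_character_,
                              statistic = NA_real_, p_value = NA_real_,
                              note = "constant covariate"))
      }
      if (is.numeric(v)) {
        a <- spearman_assoc(scores[, j], v)
        tibble::tibble(pc = j, covariate = cv, test = "spearman",
                       statistic = a$rho, p_value = a$p_value,
                       note = NA_character_)
      } else {
        kw <- stats::kruskal.test(scores[, j], factor(v))
        tibble::tibble(pc = j, covariate = cv, test = "kruskal-wallis",
                       statistic = unname(kw$statistic),
                       p_value = kw$p.value, note = NA_character_)
      }
    })
  })
}
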