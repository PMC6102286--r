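#' Pooled two-sample spread of a gene's delta values
#'
#' The gene-specific scale used in the denominator of the relative
#' difference: `s = sqrt((1/n_H + 1/n_L) * (SS_H + SS_L) / (n_H + n_L - 2))`,
#' i.e. the pooled standard error of the difference in group means.
#'
#' @param values_high,values_low Numeric vectors (each of length >= 2) of a
#'   gene's delta expression in the high and low responder groups.
#' @return A single non-negative number.
#' @export
pooled_sd <- function(values_high, values_low) {
  n_h <- length(values_high)
  n_l <- length(values_low)
  if (n_h < 2 || n_l < 2) stop("each group needs >= 2 values", call. = FALSE)
  ss <- sum((values_high - mean(values_high))^2) +
    sum((values_low - mean(values_low))^2)
  sqrt((1 / n_h + 1 / n_l) * ss / (n_h + n_l - 2))
}

#' Moderated relative difference
#'
#' The signature statistic `d = (mean_high - mean_low) / (s + s0)`: a
#' two-sample contrast whose denominator is inflated by the fudge factor `s0`
#' so that genes with tiny spread cannot reach huge `d` by chance.  With
#' `s0 = 0` it reduces to the classical pooled two-sample t statistic.
#'
#' @param mean_high,mean_low Group means of the gene's delta expression.
#' @param s Pooled spread from [pooled_sd()] (`>= 0`).
#' @param s0 Fudge factor (`>= 0`); `s + s0` must be positive.
#' @return The (vectorised) statistic.
#' @export
relative_difference <- function(mean_high, mean_low, s, s0) {
  if (any(s < 0) || any(s0 < 0)) stop("s and s0 must be non-negative", call. = FALSE)
  if (any(s + s0 == 0)) stop("s + s0 must be positive", call. = FALSE)
  (mean_high - mean_low) / (s + s0)
}

#' Estimate the fudge factor s0
#'
#' Default method `"cv_min"` is the coefficient-of-variation minimisation
#' recipe: candidate values are the 0, 5, ..., 100th percentiles of the
#' per-gene spreads `s(i)`; for each candidate the statistic `d` is
#' recomputed, genes are binned into approximately 100 equal-count windows by
#' `s(i)`, and the candidate minimising the coefficient of variation of the
#' per-window median absolute deviation of `d` wins (ties: smallest
#' candidate).  `"percentile"` takes the `q`-th percentile of `s(i)`;
#' `"fixed"` uses `value` as given.
#'
#' @param mean_diff Per-gene `mean_high - mean_low`.
#' @param s Per-gene pooled spreads.
#' @param method `"cv_min"` (default), `"percentile"` or `"fixed"`.
#' @param q Percentile in `[0, 100]` for `method = "percentile"`.
#' @param value Explicit value for `method = "fixed"`.
#' @return The chosen `s0` (single number).
#' @export
estimate_s0 <- function(mean_diff, s, method = c("cv_min", "percentile", "fixed"),
                        q = 50, value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || value < 0) stop("fixed method needs value >= 0", call. = FALSE)
    return(value)
  }
  if (all(s == 0)) stop("all per-gene spreads are zero", call. = FALSE)
  if (method == "percentile") {
    return(unname(stats::quantile(s, q / 100)))
  }
  n <- length(s)
  if (n < 20) stop("cv_min needs >= 20 genes", call. = FALSE)
  candidates <- unname(stats::quantile(s, seq(0, 1, by = 0.05)))
  n_windows <- min(100L, max(2L, n %/% 20L))
  win <- ceiling(rank(s, ties.method = "first") / (n / n_windows))
  cv <- vapply(candidates, function(a) {
    denom <- s + a
    d <- ifelse(denom > 0, mean_diff / denom, NA_real_)
    mads <- tapply(d, win, stats::mad, na.rm = TRUE)
    m <- mean(mads, na.rm = TRUE)
    if (!is.finite(m) || m == 0) return(Inf)
    stats::sd(mads, na.rm = TRUE) / m
  }, numeric(1))
  if (all(!is.finite(cv))) return(min(candidates))
  candidates[which(cv == min(cv))][1L]  # candidates ascending: first = smallest
}

# vectorised group summaries used by the signature and its permutations
group_stats <- function(x, is_high, is_low) {
  n_h <- sum(is_high)
  n_l <- sum(is_low)
  mh <- rowMeans(x[, is_high, drop = FALSE])
  ml <- rowMeans(x[, is_low, drop = FALSE])
  ssh <- rowSums((x[, is_high, drop = FALSE] - mh)^2)
  ssl <- rowSums((x[, is_low, drop = FALSE] - ml)^2)
  s <- sqrt((1 / n_h + 1 / n_l) * (ssh + ssl) / (n_h + n_l - 2))
  list(mean_high = mh, mean_low = ml, s = s, n_high = n_h, n_low = n_l)
}

normalize_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels must be named by sample id or aligned with the samples",
         call. = FALSE)
  }
  labels <- as.character(labels)
  labels[is.na(labels)] <- "none"
  bad <- setdiff(unique(labels), c("high", "low", "none"))
  if (length(bad)) {
    stop("labels must be 'high', 'low' or 'none'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  labels
}

#' Signature-gene table: moderated relative differences for every gene
#'
#' Computes, over the labeled (high/low) samples only, each gene's group
#' means, pooled spread, moderated relative difference `d` with one
#' table-level fudge factor `s0`, and the rank by `|d|` (descending, ties by
#' gene id).  Optionally appends permutation-based empirical p-values.
#'
#' @param delta A [delta_expression()] (or genes x samples matrix).
#' @param labels Per-sample responder classes (`"high"`, `"low"`, `"none"`),
#'   either named by sample id or aligned with the matrix columns; `"none"`
#'   samples never enter the statistic.
#' @param s0_method,q,value Passed to [estimate_s0()].
#' @param B Number of label permutations for empirical p-values (0 = skip).
#' @param seed Seed for the permutations.
#' @param pool_null Passed to [permutation_pvalues()].
#' @return A tibble of class `signature_table`, ordered by rank, with columns
#'   `gene_id`, `mean_high`, `mean_low`, `pooled_sd`, `d`, `rank` (and
#'   `p_empirical`, `floor_flag` when `B > 0`); attributes `s0`, `n_high`,
#'   `n_low`, `B`, `p_floor`, `seed`.
#' @export
compute_signature <- function(delta, labels, s0_method = "cv_min", q = 50,
                              value = NULL, B = 0L, seed = 1L,
                              pool_null = FALSE) {
  delta <- as_delta(delta)
  x <- delta$values
  labels <- normalize_labels(labels, colnames(x))
  is_high <- labels == "high"
  is_low <- labels == "low"
  if (sum(is_high) < 2 || sum(is_low) < 2) {
    stop("need >= 2 samples in each of the high and low classes", call. = FALSE)
  }
  gs <- group_stats(x, is_high, is_low)
  s0 <- estimate_s0(gs$mean_high - gs$mean_low, gs$s, method = s0_method,
                    q = q, value = value)
  if (any(gs$s + s0 == 0)) {
    warning(sum(gs$s + s0 == 0), " gene(s) with s + s0 = 0; d set to NA")
  }
  denom <- gs$s + s0
  d <- ifelse(denom > 0, (gs$mean_high - gs$mean_low) / denom, NA_real_)
  ord <- order(-abs(d), rownames(x))
  tab <- tibble::tibble(
    gene_id = rownames(x),
    mean_high = unname(gs$mean_high),
    mean_low = unname(gs$mean_low),
    pooled_sd = unname(gs$s),
    d = unname(d)
  )
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  tab <- tab[ord, ]
  attr(tab, "s0") <- s0
  attr(tab, "n_high") <- gs$n_high
  attr(tab, "n_low") <- gs$n_low
  attr(tab, "seed") <- seed
  class(tab) <- c("signature_table", class(tab))
  if (B > 0) {
    p <- permutation_pvalues(delta, labels, B = B, seed = seed, s0 = s0,
                             pool_null = pool_null)
    tab <- dplyr::left_join(
      tab, dplyr::select(p, "gene_id", "n_exceed", "p_empirical", "floor_flag"),
      by = "gene_id")
    class(tab) <- c("signature_table", setdiff(class(tab), "signature_table"))
    attr(tab, "s0") <- s0
    attr(tab, "n_high") <- gs$n_high
    attr(tab, "n_low") <- gs$n_low
    attr(tab, "seed") <- seed
    attr(tab, "B") <- as.integer(B)
    attr(tab, "p_floor") <- attr(p, "p_floor")
  }
  tab
}

#' Permutation-based empirical p-values for the relative difference
#'
#' For each of `B` uniform random permutations of the high/low labels over
#' the labeled samples, recomputes `d` for every gene with the fudge factor
#' held at its observed-data value; the empirical p-value is the fraction of
#' permutations whose `|d|` reaches the observed `|d|`.  A gene whose
#' observed `|d|` exceeds every permuted value is reported at `p_empirical =
#' 0` with `floor_flag = TRUE`: its p-value is below the resolution floor
#' `1/B` of the permutation scheme.
#'
#' @param delta A [delta_expression()] or matrix.
#' @param labels As in [compute_signature()].
#' @param B Number of permutations (`>= 1`).
#' @param seed RNG seed.
#' @param s0 Fudge factor; defaults to re-estimating from the observed data
#'   via [estimate_s0()] with `s0_method`.
#' @param s0_method Method for that estimate when `s0` is `NULL`.
#' @param pool_null Compare each gene's observed `|d|` against the null
#'   values pooled across all genes and permutations (resolution `1/(B *
#'   n_genes)`) instead of the per-gene null (the default).
#' @return A tibble `gene_id`, `d_obs`, `n_exceed`, `p_empirical`,
#'   `floor_flag`, with attributes `B`, `p_floor`, `s0`, `seed`.
#' @export
permutation_pvalues <- function(delta, labels, B = 5000L, seed = 1L,
                                s0 = NULL, s0_method = "cv_min",
                                pool_null = FALSE) {
  delta <- as_delta(delta)
  x <- delta$values
  labels <- normalize_labels(labels, colnames(x))
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  keep <- labels != "none"
  x <- x[, keep, drop = FALSE]
  lab <- labels[keep]
  n_h <- sum(lab == "high")
  n_l <- sum(lab == "low")
  if (n_h < 2 || n_l < 2) stop("need both classes with >= 2 samples", call. = FALSE)
  n <- n_h + n_l
  if (choose(n, n_h) < B) {
    warning("only ", choose(n, n_h), " distinct label permutations exist; ",
            "B = ", B, " resamples them with repetition")
  }
  obs <- group_stats(x, lab == "high", lab == "low")
  if (is.null(s0)) {
    s0 <- estimate_s0(obs$mean_high - obs$mean_low, obs$s, method = s0_method)
  }
  d_abs_obs <- abs(obs$mean_high - obs$mean_low) / (obs$s + s0)
  x2 <- x^2
  const <- (1 / n_h + 1 / n_l) / (n - 2)
  exceed <- numeric(nrow(x))
  obs_sorted <- sort(d_abs_obs)
  ord_back <- rank(d_abs_obs, ties.method = "first")
  with_seed(seed, {
    for (b in seq_len(B)) {
      ih <- numeric(n)
      ih[sample.int(n, n_h)] <- 1
      il <- 1 - ih
      sum_h <- drop(x %*% ih); sum_l <- drop(x %*% il)
      ss_h <- drop(x2 %*% ih) - sum_h^2 / n_h
      ss_l <- drop(x2 %*% il) - sum_l^2 / n_l
      s_b <- sqrt(pmax(const * (ss_h + ss_l), 0))
      d_b <- abs(sum_h / n_h - sum_l / n_l) / (s_b + s0)
      if (pool_null) {
        # per gene, count null values (all genes, this permutation) >= obs
        sv <- sort(d_b)
        cnt <- length(sv) - findInterval(obs_sorted, sv, left.open = TRUE)
        exceed <- exceed + cnt[ord_back]
      } else {
        exceed <- exceed + (d_b >= d_abs_obs)
      }
    }
  })
  denom <- if (pool_null) B * nrow(x) else B
  out <- tibble::tibble(
    gene_id = rownames(x),
    d_obs = unname((obs$mean_high - obs$mean_low) / (obs$s + s0)),
    n_exceed = as.integer(unname(exceed)),
    p_empirical = unname(exceed / denom),
    floor_flag = unname(exceed == 0)
  )
  attr(out, "B") <- as.integer(B)
  attr(out, "p_floor") <- 1 / denom
  attr(out, "s0") <- s0
  attr(out, "seed") <- seed
  out
}

#' Top-k signature genes
#'
#' The first `k` gene ids of a [compute_signature()] table in rank order
#' (largest `|d|` first; ties already resolved by gene id in the ranking).
#'
#' @param signature A `signature_table`.
#' @param k Panel size (`<=` number of genes).
#' @return Character vector of `k` gene ids.
#' @export
top_k_genes <- function(signature, k) {
  stopifnot(inherits(signature, "signature_table"))
  if (k > nrow(signature)) stop("k exceeds the number of genes", call. = FALSE)
  signature$gene_id[order(signature$rank)][seq_len(k)]
}
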