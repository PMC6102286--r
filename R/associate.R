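#' Delta-log change of a clinical phenotype
#'
#' The treatment effect on the log scale: `log(mean(on-treatment values)) -
#' log(mean(pre-treatment values))`.  Natural logarithms; the downstream
#' rank-based statistics are invariant to the base.
#'
#' @param pre_values,post_values Positive phenotype measurements before and
#'   on treatment (each side may hold one or more replicates, e.g. two
#'   pre-treatment visits).
#' @return A single dimensionless log-ratio.
#' @export
delta_log_phenotype <- function(pre_values, post_values) {
  if (length(pre_values) < 1 || length(post_values) < 1) {
    stop("need at least one value on each side", call. = FALSE)
  }
  if (any(pre_values <= 0) || any(post_values <= 0)) {
    stop("phenotype values must be positive", call. = FALSE)
  }
  log(mean(post_values)) - log(mean(pre_values))
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Spearman's rho with average ranks for ties; the two-sided p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom (p = 0 at `|rho| = 1`).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with finite values.
#' @return A list with `rho`, `p_value`, `n`, and `constant` flagging an
#'   undefined correlation (a constant input), in which case `rho` and
#'   `p_value` are `NA`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, constant = TRUE))
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, constant = FALSE)
}

#' Bonferroni adjustment
#'
#' `min(1, m_tests * p_raw)`, the family-wise correction used over the
#' signature panel.
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param m_tests Number of tests in the family (`>= 1`).
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p_raw, m_tests) {
  if (any(p_raw < 0 | p_raw > 1)) stop("p_raw must lie in [0, 1]", call. = FALSE)
  if (m_tests < 1) stop("m_tests must be >= 1", call. = FALSE)
  pmin(1, m_tests * p_raw)
}

#' Scan a signature panel for association with a phenotype
#'
#' Correlates each panel gene's delta expression with a per-sample phenotype
#' (e.g. the cellular cholesterol-ester delta) by [spearman_assoc()], and
#' Bonferroni-adjusts over the panel size.
#'
#' @param delta A [delta_expression()] or genes x samples matrix.
#' @param panel Character vector of panel gene ids.
#' @param phenotype Per-sample phenotype values, named by sample id (or
#'   aligned with the matrix columns); samples with missing phenotype are
#'   dropped.
#' @param phenotype_name Label recorded in the output.
#' @return A tibble (one row per panel gene) with `gene_id`, `phenotype`,
#'   `n`, `rho`, `p_raw`, `p_adjusted`, `m_tests`, sorted by `p_adjusted`
#'   then `p_raw` ascending.
#' @export
panel_phenotype_scan <- function(delta, panel, phenotype,
                                 phenotype_name = "phenotype") {
  delta <- as_delta(delta)
  if (length(panel) == 0) stop("panel is empty", call. = FALSE)
  missing <- setdiff(panel, rownames(delta$values))
  if (length(missing)) {
    stop("panel genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ids <- colnames(delta$values)
  if (!is.null(names(phenotype))) {
    phenotype <- phenotype[ids]
  } else if (length(phenotype) != length(ids)) {
    stop("phenotype must be named by sample id or aligned with the samples",
         call. = FALSE)
  }
  keep <- is.finite(phenotype)
  if (sum(keep) < 3) stop("phenotype available for < 3 samples", call. = FALSE)
  m <- length(panel)
  res <- purrr::map_dfr(panel, function(g) {
    a <- spearman_assoc(delta$values[g, keep], phenotype[keep])
    tibble::tibble(gene_id = g, phenotype = phenotype_name, n = a$n,
                   rho = a$rho, p_raw = a$p_value,
                   p_adjusted = if (is.na(a$p_value)) NA_real_
                                else bonferroni(a$p_value, m),
                   m_tests = m)
  })
  dplyr::arrange(res, p_adjusted, p_raw, gene_id)
}

#' Two-sided pooled-variance t-test between responder groups
#'
#' The group-difference test used for phenotype contrasts between high and
#' low responders (classical two-sample Student t with pooled variance).
#'
#' @param values_high,values_low Numeric vectors, each with `>= 2` values.
#' @return A list with `statistic` (t, positive when the high group is
#'   larger), `p_value`, `df`.
#' @export
group_difference_test <- function(values_high, values_low) {
  if (length(values_high) < 2 || length(values_low) < 2) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  if (stats::sd(values_high) == 0 && stats::sd(values_low) == 0 &&
      mean(values_high) == mean(values_low)) {
    return(list(statistic = 0, p_value = 1,
                df = length(values_high) + length(values_low) - 2))
  }
  tt <- stats::t.test(values_high, values_low, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Residualize a response on covariates
#'
#' Least-squares adjustment used before correlating a clinical change score
#' with expression changes (e.g. plasma LDLC change adjusted for age and
#' smoking): returns the residuals of `response ~ covariates`, re-centered to
#' the response mean.
#'
#' @param response Numeric vector.
#' @param data Data frame of covariates aligned with `response`.
#' @param covariates Column names in `data` to adjust for.
#' @return Adjusted response vector.
#' @export
residualize <- function(response, data, covariates) {
  stopifnot(is.data.frame(data), length(response) == nrow(data))
  if (!all(covariates %in% names(data))) {
    stop("missing covariates: ",
         paste(setdiff(covariates, names(data)), collapse = ", "), call. = FALSE)
  }
  mm <- stats::model.matrix(
    stats::reformulate(covariates), data = data)
  fit <- stats::lm.fit(mm, response)
  fit$residuals + mean(response)
}
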