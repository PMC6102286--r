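#' Delta-expression container
#'
#' A `delta_expression` wraps a genes x samples matrix of statin-minus-control
#' variance-stabilized expression changes together with provenance flags that
#' record what has been done to it (quantile normalization, batch adjustment,
#' number of principal components regressed out).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be finite.
#' @param quantile_normalized,batch_adjusted Logical provenance flags.
#' @param n_pcs_removed Non-negative integer provenance count.
#'
#' @return An object of class `delta_expression`.
#' @export
delta_expression <- function(values, quantile_normalized = FALSE,
                             batch_adjusted = FALSE, n_pcs_removed = 0L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` contains missing or non-finite entries", call. = FALSE)
  }
  structure(
    list(
      values = values,
      provenance = list(
        quantile_normalized = isTRUE(quantile_normalized),
        batch_adjusted = isTRUE(batch_adjusted),
        n_pcs_removed = as.integer(n_pcs_removed)
      )
    ),
    class = "delta_expression"
  )
}

#' @export
print.delta_expression <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<delta_expression> %d genes x %d samples [qn=%s, batch=%s, pcs_removed=%d]\n",
    nrow(x$values), ncol(x$values), p$quantile_normalized, p$batch_adjusted,
    p$n_pcs_removed))
  invisible(x)
}

#' @export
dim.delta_expression <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

as_delta <- function(x) {
  if (inherits(x, "delta_expression")) return(x)
  delta_expression(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so generator operations are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
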