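#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classifier evaluation into its ROC points
#'
#' @param x A `classifier_eval`.
#' @param ... Unused.
#' @return A tibble of `fpr`, `tpr` points.
#' @method tidy classifier_eval
#' @export
tidy.classifier_eval <- function(x, ...) x$roc_points

#' One-row summary of a classifier evaluation
#'
#' @param x A `classifier_eval`.
#' @param ... Unused.
#' @return A tibble with `auc`, `n_genes`, `n_pcs`, `n_repeats`, `n_folds`,
#'   `n_pooled`, `seed`.
#' @method glance classifier_eval
#' @export
glance.classifier_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_genes = x$n_genes, n_pcs = x$n_pcs,
                 n_repeats = x$n_repeats, n_folds = x$n_folds,
                 n_pooled = length(x$pooled_scores), seed = x$seed)
}

#' Per-dataset AUCs of a PC-correction sweep
#'
#' @param x A `pc_sweep_eval`.
#' @param ... Unused.
#' @return The summary tibble (`n_pcs`, `n_genes`, `auc`).
#' @method tidy pc_sweep_eval
#' @export
tidy.pc_sweep_eval <- function(x, ...) x$summary

#' One-row summary of a PC-correction sweep
#'
#' @param x A `pc_sweep_eval`.
#' @param ... Unused.
#' @return A tibble with `best_k`, `auc_best`, `n_datasets`.
#' @method glance pc_sweep_eval
#' @export
glance.pc_sweep_eval <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, auc_best = max(x$summary$auc),
                 n_datasets = nrow(x$summary))
}

#' Per-panel-size AUCs of a gene-count sweep
#'
#' @param x A `gene_count_sweep`.
#' @param ... Unused.
#' @return The summary tibble (`n_genes`, `auc`).
#' @method tidy gene_count_sweep
#' @export
tidy.gene_count_sweep <- function(x, ...) x$summary

#' One-row summary of a gene-count sweep
#'
#' @param x A `gene_count_sweep`.
#' @param ... Unused.
#' @return A tibble with `best_n`, `auc_best`, `n_sizes`.
#' @method glance gene_count_sweep
#' @export
glance.gene_count_sweep <- function(x, ...) {
  tibble::tibble(best_n = x$best_n, auc_best = max(x$summary$auc),
                 n_sizes = nrow(x$summary))
}

#' Signature table as a plain tibble
#'
#' @param x A `signature_table`.
#' @param ... Unused.
#' @return The per-gene tibble without the class attribute.
#' @method tidy signature_table
#' @export
tidy.signature_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "signature_table")
  tibble::as_tibble(out)
}

#' Table-level parameters of a signature fit
#'
#' @param x A `signature_table`.
#' @param ... Unused.
#' @return A tibble with `s0`, `n_high`, `n_low`, `n_genes`, `B`, `p_floor`.
#' @method glance signature_table
#' @export
glance.signature_table <- function(x, ...) {
  tibble::tibble(
    s0 = attr(x, "s0"), n_high = attr(x, "n_high"), n_low = attr(x, "n_low"),
    n_genes = nrow(x),
    B = attr(x, "B") %||% NA_integer_,
    p_floor = attr(x, "p_floor") %||% NA_real_)
}

#' @importFrom rlang %||%
NULL
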