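#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve of a classifier evaluation
#'
#' @param object A `classifier_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot classifier_eval
#' @export
autoplot.classifier_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f (%d genes, %d pooled test folds)",
                                  object$auc, object$n_genes,
                                  object$n_repeats)) +
    ggplot2::theme_minimal()
}

#' AUC against the number of corrected PCs
#'
#' @param object A `pc_sweep_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pc_sweep_eval
#' @export
autoplot.pc_sweep_eval <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$n_pcs, y = .data$auc)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dotted",
                        colour = "#b2182b") +
    ggplot2::labs(x = "PCs regressed out", y = "Cross-ancestry AUC",
                  title = sprintf("Best correction depth: %d PCs",
                                  object$best_k)) +
    ggplot2::theme_minimal()
}

#' AUC against the signature-panel size
#'
#' @param object A `gene_count_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_count_sweep
#' @export
autoplot.gene_count_sweep <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$n_genes, y = .data$auc)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_n, linetype = "dotted",
                        colour = "#b2182b") +
    ggplot2::labs(x = "Signature genes in panel", y = "Cross-ancestry AUC",
                  title = sprintf("Best panel size: %d genes", object$best_n)) +
    ggplot2::theme_minimal()
}

#' Heatmap of PC-covariate association p-values
#'
#' Visualises [pc_covariate_diagnostics()]: -log10 p per (PC, covariate),
#' the standard check that confounder proxies fade as correction deepens.
#'
#' @param diagnostics Tibble from [pc_covariate_diagnostics()].
#' @return A ggplot.
#' @export
plot_pc_diagnostics <- function(diagnostics) {
  diagnostics$neglog10p <- -log10(pmax(diagnostics$p_value, 1e-16))
  ggplot2::ggplot(diagnostics,
                  ggplot2::aes(x = .data$pc, y = .data$covariate,
                               fill = .data$neglog10p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 name = expression(-log[10](p))) +
    ggplot2::labs(x = "Principal component", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of a gene's delta expression against a phenotype change
#'
#' Companion plot for the association scan (e.g. cholesterol-ester delta
#' against the top signature gene), annotated with Spearman's rho.
#'
#' @param delta A [delta_expression()] or matrix.
#' @param gene Gene id.
#' @param phenotype Per-sample phenotype values named by sample id.
#' @param phenotype_name Axis label.
#' @return A ggplot.
#' @export
plot_gene_phenotype <- function(delta, gene, phenotype,
                                phenotype_name = "phenotype delta") {
  delta <- as_delta(delta)
  ids <- intersect(colnames(delta$values),
                   if (is.null(names(phenotype))) colnames(delta$values)
                   else names(phenotype))
  x <- delta$values[gene, ids]
  y <- if (is.null(names(phenotype))) phenotype else phenotype[ids]
  a <- spearman_assoc(x, y)
  df <- tibble::tibble(expression_delta = unname(x), phenotype = unname(y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expression_delta,
                                   y = .data$phenotype)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#2166ac") +
    ggplot2::labs(x = sprintf("%s expression change", gene),
                  y = phenotype_name,
                  title = sprintf("Spearman rho = %.3f (n = %d)", a$rho, a$n)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
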