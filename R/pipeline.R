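#' Configuration of an end-to-end pipeline run
#'
#' Either a [simulation_config()] (simulated study) or file paths to real
#' statin/control expression TSVs plus a phenotype TSV — exactly one of the
#' two.  The remaining fields set every stage's parameters.
#'
#' @param simulation A [simulation_config()], or `NULL` when reading files.
#' @param statin_path,control_path,phenotype_path Input TSVs (real-data mode).
#' @param discovery_ancestry,validation_ancestry Ancestry codes used for
#'   signature discovery and cross-ancestry validation.
#' @param k_max Depth of the progressive PC-correction sweep.
#' @param pc_threshold Minimum per-PC variance share for [select_n_pcs()]
#'   (diagnostic; the sweep always emits `k_max` datasets).
#' @param n_top_genes Panel size for the PC sweep.
#' @param n_gene_grid Panel sizes for the refinement sweep.
#' @param B Label permutations for empirical p-values.
#' @param n_repeats,n_folds Repeated-split evaluation settings.
#' @param s0_method Fudge-factor method.
#' @param train_on_discovery,recompute_pca_per_k,pooled_null Optional
#'   behaviour switches (see [pc_sweep_eval()], [pc_correction_sweep()],
#'   [permutation_pvalues()]).
#' @param association_phenotype Phenotype column scanned against the final
#'   panel (default the cellular cholesterol-ester delta).
#' @param output_dir If non-`NULL`, all tables, a JSON summary and a log are
#'   written there.
#' @param seed Pipeline seed (also overrides the simulation seed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       statin_path = NULL, control_path = NULL,
                       phenotype_path = NULL,
                       discovery_ancestry = "EA", validation_ancestry = "AA",
                       k_max = 25L, pc_threshold = 0.005,
                       n_top_genes = 100L, n_gene_grid = 70:90,
                       B = 5000L, n_repeats = 5000L, n_folds = 10L,
                       s0_method = "cv_min", train_on_discovery = FALSE,
                       recompute_pca_per_k = FALSE, pooled_null = FALSE,
                       association_phenotype = "ce_delta",
                       output_dir = NULL, seed = 1L) {
  simulate <- is.null(statin_path)
  if (!simulate && (is.null(control_path) || is.null(phenotype_path))) {
    stop("real-data mode needs statin_path, control_path and phenotype_path",
         call. = FALSE)
  }
  if (!simulate && !is.null(simulation)) simulation <- NULL
  if (simulate && is.null(simulation)) simulation <- simulation_config()
  if (any(c(k_max, B, n_repeats, n_folds) < 1)) {
    stop("k_max, B, n_repeats and n_folds must be positive", call. = FALSE)
  }
  if (simulate) simulation$seed <- as.integer(seed)
  structure(
    list(simulate = simulate, simulation = simulation,
         statin_path = statin_path, control_path = control_path,
         phenotype_path = phenotype_path,
         discovery_ancestry = discovery_ancestry,
         validation_ancestry = validation_ancestry,
         k_max = as.integer(k_max), pc_threshold = pc_threshold,
         n_top_genes = as.integer(n_top_genes),
         n_gene_grid = as.integer(n_gene_grid), B = as.integer(B),
         n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
         s0_method = s0_method, train_on_discovery = train_on_discovery,
         recompute_pca_per_k = recompute_pca_per_k, pooled_null = pooled_null,
         association_phenotype = association_phenotype,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full signature-discovery pipeline
#'
#' Executes, in order: simulate (or load) the paired expression data and
#' phenotypes; delta computation, quantile normalization and batch
#' regression; the progressive PC-correction sweep; per-dataset signature
#' discovery on the discovery-ancestry tails and cross-ancestry classifier
#' evaluation (AUC vs number of PCs); panel-size refinement at the best
#' correction depth; permutation p-values for the final signature; and the
#' panel-phenotype association scan.  Each stage is seeded from the run seed,
#' so a fixed configuration reproduces the result bundle byte for byte.
#'
#' @param config A [run_config()].
#' @return A list of class `statin_run` with elements `cohort`, `delta`
#'   (batch-adjusted, normalized), `pca`, `selected_k_rule` (the 0.5 percent
#'   rule's choice), `pc_sweep`, `best_k`, `gene_sweep`, `best_n`,
#'   `signature` (with empirical p-values), `panel`, `association`,
#'   `diagnostics` (PC-covariate table), and `summary` (named list of the
#'   headline numbers).  If `config$output_dir` is set, all tables are
#'   written as TSV plus a `summary.json` and `run.log`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)  # no timestamps: bundles stay byte-reproducible
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  say("run_pipeline: seed %d, %s mode", config$seed,
      if (config$simulate) "simulation" else "file")

  if (config$simulate) {
    study <- stage("simulate", simulate_study(config$simulation))
    cohort <- study$cohort
    statin <- study$statin
    control <- study$control
  } else {
    statin <- stage("load", read_expression_tsv(config$statin_path))
    control <- stage("load", read_expression_tsv(config$control_path))
    cohort <- stage("load", read_phenotype_tsv(config$phenotype_path))
    study <- NULL
  }

  delta <- stage("preprocess", {
    d <- compute_delta(statin, control)
    d <- quantile_normalize(d)
    regress_out_batch(d, stats::setNames(cohort$batch, cohort$sample_id))
  })
  pca <- stage("preprocess", pca_samples(delta))
  k_rule <- select_n_pcs(pca$variance_explained,
                         threshold = config$pc_threshold,
                         cap = config$k_max)
  say("PCA: %d components; 0.5%%-rule selects k = %d", ncol(pca$scores), k_rule)
  k_max <- min(config$k_max, ncol(pca$scores) - 1L)
  datasets <- stage("preprocess",
                    pc_correction_sweep(delta, k_max,
                                        recompute_pca = config$recompute_pca_per_k))
  say("PC sweep: %d corrected datasets", length(datasets))

  disc <- responder_labels(cohort, config$discovery_ancestry)
  val <- responder_labels(cohort, config$validation_ancestry)
  sweep <- stage("classify", pc_sweep_eval(
    datasets, disc, val, n_top_genes = config$n_top_genes,
    n_repeats = config$n_repeats, n_folds = config$n_folds,
    seed = config$seed + 100L, s0_method = config$s0_method,
    train_on_discovery = config$train_on_discovery))
  best_k <- sweep$best_k
  say("best correction depth: k = %d (AUC = %.3f)", best_k,
      max(sweep$summary$auc))

  best_ds <- datasets[[best_k]]
  gsweep <- stage("classify", gene_count_sweep(
    best_ds, disc, val, n_grid = config$n_gene_grid,
    n_repeats = config$n_repeats, n_folds = config$n_folds,
    seed = config$seed + 200L, s0_method = config$s0_method,
    train_on_discovery = config$train_on_discovery))
  best_n <- gsweep$best_n
  say("best panel size: n = %d (AUC = %.3f)", best_n, max(gsweep$summary$auc))

  signature <- stage("signature", compute_signature(
    best_ds, disc, s0_method = config$s0_method, B = config$B,
    seed = config$seed + 300L, pool_null = config$pooled_null))
  n_floor <- sum(signature$floor_flag, na.rm = TRUE)
  say("signature: s0 = %.4f, %d genes at the empirical-p floor %.2g",
      attr(signature, "s0"), n_floor, attr(signature, "p_floor"))

  panel <- top_k_genes(signature, best_n)
  association <- NULL
  if (config$association_phenotype %in% names(cohort)) {
    disc_cohort <- cohort[cohort$ancestry == config$discovery_ancestry, ]
    phen <- stats::setNames(disc_cohort[[config$association_phenotype]],
                            disc_cohort$sample_id)
    disc_delta <- best_ds
    disc_delta$values <- best_ds$values[, disc_cohort$sample_id, drop = FALSE]
    association <- stage("associate", panel_phenotype_scan(
      disc_delta, panel, phen,
      phenotype_name = config$association_phenotype))
    say("association: top gene %s (rho = %.3f, adjusted p = %.3g)",
        association$gene_id[1], association$rho[1], association$p_adjusted[1])
  }

  diagnostics <- stage("preprocess",
                       pc_covariate_diagnostics(pca, cohort,
                                                n_pcs = min(20L, ncol(pca$scores))))

  summary <- list(
    seed = config$seed,
    n_datasets = length(datasets),
    k_rule_selected = k_rule,
    best_k = best_k,
    auc_best_k = max(sweep$summary$auc),
    auc_k1 = sweep$summary$auc[1],
    best_n = best_n,
    auc_best_n = max(gsweep$summary$auc),
    s0 = attr(signature, "s0"),
    B = config$B,
    p_floor = attr(signature, "p_floor"),
    n_floor_genes = n_floor,
    top_association_gene = if (!is.null(association)) association$gene_id[1] else NA,
    top_association_rho = if (!is.null(association)) association$rho[1] else NA,
    top_association_p_adjusted = if (!is.null(association)) association$p_adjusted[1] else NA
  )
  if (!is.null(study)) {
    summary$planted_in_panel <- length(intersect(panel, study$planted_genes))
    summary$ce_gene <- study$ce_gene
  }

  out <- structure(
    list(config = config, cohort = cohort, delta = delta, pca = pca,
         selected_k_rule = k_rule, pc_sweep = sweep, best_k = best_k,
         gene_sweep = gsweep, best_n = best_n, signature = signature,
         panel = panel, association = association, diagnostics = diagnostics,
         planted_genes = if (!is.null(study)) study$planted_genes else NULL,
         ce_gene = if (!is.null(study)) study$ce_gene else NULL,
         summary = summary, log = log_lines),
    class = "statin_run"
  )
  if (!is.null(config$output_dir)) write_run_bundle(out, config$output_dir)
  out
}

write_run_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phenotype_tsv(run$cohort, file.path(dir, "phenotypes.tsv"))
  write_expression_tsv(run$delta, file.path(dir, "delta_expression.tsv"))
  readr::write_tsv(run$pc_sweep$summary, file.path(dir, "pc_sweep.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$gene_sweep$summary, file.path(dir, "gene_sweep.tsv"),
                   progress = FALSE)
  sig <- tibble::as_tibble(run$signature)
  readr::write_tsv(sig, file.path(dir, "signature.tsv"), progress = FALSE)
  writeLines(run$panel, file.path(dir, "panel_genes.txt"))
  if (!is.null(run$planted_genes)) {
    writeLines(run$planted_genes, file.path(dir, "planted_genes_truth.txt"))
  }
  if (!is.null(run$association)) {
    readr::write_tsv(run$association, file.path(dir, "association.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(run$diagnostics, file.path(dir, "pc_diagnostics.tsv"),
                   progress = FALSE)
  best <- run$pc_sweep$evals[[run$best_k]]
  readr::write_tsv(best$roc_points, file.path(dir, "roc_best_k.tsv"),
                   progress = FALSE)
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  cfg <- run$config
  cfg$simulation <- unclass(cfg$simulation)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.statin_run <- function(x, ...) {
  cat(sprintf(
    paste0("<statin_run> %d datasets; best k = %d (AUC = %.3f); ",
           "panel n = %d (AUC = %.3f)\n"),
    x$summary$n_datasets, x$best_k, x$summary$auc_best_k, x$best_n,
    x$summary$auc_best_n))
  if (!is.null(x$association)) {
    cat(sprintf("  top association: %s rho = %.3f, Bonferroni p = %.3g\n",
                x$association$gene_id[1], x$association$rho[1],
                x$association$p_adjusted[1]))
  }
  invisible(x)
}
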