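#' Simulation configuration for the two-ancestry statin-response study design
#'
#' Bundles every parameter of the synthetic-data generator: cohort sizes for
#' the tail-selected high/low LDL-cholesterol responders of the two ancestry
#' groups, the planted signature-gene effect, latent confounder structure,
#' batch effect, noise level, and the coupling of one designated signature
#' gene to the cellular cholesterol-ester change.
#'
#' Cohort sizes and the responder-class means/sds of the LDLC percent change
#' default to the clinical characteristics of the study design this generator
#' emulates: 25 high / 25 low European American (EA) responders
#' (-59.1 +/- 3.9 percent vs -22.2 +/- 8.0 percent) and 12 high / 14 low
#' African American (AA) responders (-57.5 +/- 3.2 vs -21.5 +/- 6.5), plus 54
#' non-tail EA background samples so the EA cohort totals 104.
#'
#' @param n_genes Number of genes simulated.
#' @param n_signature Number of planted signature genes whose statin-induced
#'   expression change differs between responder classes.
#' @param n_ea_high,n_ea_low,n_aa_high,n_aa_low Tail cohort sizes.
#' @param n_background_samples Non-tail EA samples (responder class "none").
#' @param effect_size Difference in mean delta expression between high and low
#'   responders at each planted gene, in variance-stabilized units.
#' @param n_confounders Number of latent confounding factors.
#' @param confounder_loading_sd SD of per-gene loadings on each confounder.
#' @param covariate_confounder_corr Correlation in `[0, 1]` between each
#'   measured covariate's latent liability and its paired confounder.
#' @param batch_effect_sd SD of per-gene, per-batch offsets.
#' @param noise_sd SD of the i.i.d. Gaussian noise on each delta value.
#' @param ce_coupling Signed coefficient linking the designated signature
#'   gene's (standardized) delta to the cholesterol-ester delta; negative by
#'   default (gene up, cholesterol ester down).
#' @param ce_class_offset Responder-class offset on the cholesterol-ester
#'   delta (high responders shifted down by this amount, low responders up).
#' @param ce_noise_sd SD of the noise on the cholesterol measurements.
#' @param class_mean,class_sd Named numeric vectors (`ea_high`, `ea_low`,
#'   `aa_high`, `aa_low`) of the LDLC percent-change distributions.
#' @param seed Integer seed; a fixed seed makes every generator operation
#'   byte-reproducible.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_signature = 80L,
                              n_ea_high = 25L, n_ea_low = 25L,
                              n_aa_high = 12L, n_aa_low = 14L,
                              n_background_samples = 54L,
                              effect_size = 1.5,
                              n_confounders = 3L,
                              confounder_loading_sd = 3,
                              covariate_confounder_corr = 0.5,
                              batch_effect_sd = 0.5,
                              noise_sd = 1,
                              ce_coupling = -0.55,
                              ce_class_offset = 0.25,
                              ce_noise_sd = 1,
                              class_mean = c(ea_high = -59.1, ea_low = -22.2,
                                             aa_high = -57.5, aa_low = -21.5),
                              class_sd = c(ea_high = 3.9, ea_low = 8.0,
                                           aa_high = 3.2, aa_low = 6.5),
                              seed = 1L) {
  counts <- c(n_genes = n_genes, n_signature = n_signature,
              n_ea_high = n_ea_high, n_ea_low = n_ea_low,
              n_aa_high = n_aa_high, n_aa_low = n_aa_low)
  if (any(counts <= 0)) {
    stop("counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "), call. = FALSE)
  }
  if (n_background_samples < 0) stop("n_background_samples must be >= 0", call. = FALSE)
  if (n_signature > n_genes) stop("n_signature must be <= n_genes", call. = FALSE)
  if (n_confounders < 0) stop("n_confounders must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (any(class_sd < 0)) stop("class sds must be non-negative", call. = FALSE)
  if (covariate_confounder_corr < 0 || covariate_confounder_corr > 1) {
    stop("covariate_confounder_corr must lie in [0, 1]", call. = FALSE)
  }
  nm <- c("ea_high", "ea_low", "aa_high", "aa_low")
  if (!all(nm %in% names(class_mean)) || !all(nm %in% names(class_sd))) {
    stop("class_mean/class_sd need names ", paste(nm, collapse = ", "), call. = FALSE)
  }
  # high responders reduce LDLC more, i.e. sit strictly below the low class
  if (class_mean[["ea_high"]] >= class_mean[["ea_low"]] ||
      class_mean[["aa_high"]] >= class_mean[["aa_low"]]) {
    stop("high-responder class mean must be below the low-responder mean",
         call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), n_signature = as.integer(n_signature),
         n_ea_high = as.integer(n_ea_high), n_ea_low = as.integer(n_ea_low),
         n_aa_high = as.integer(n_aa_high), n_aa_low = as.integer(n_aa_low),
         n_background_samples = as.integer(n_background_samples),
         effect_size = effect_size, n_confounders = as.integer(n_confounders),
         confounder_loading_sd = confounder_loading_sd,
         covariate_confounder_corr = covariate_confounder_corr,
         batch_effect_sd = batch_effect_sd, noise_sd = noise_sd,
         ce_coupling = ce_coupling, ce_class_offset = ce_class_offset,
         ce_noise_sd = ce_noise_sd,
         class_mean = class_mean[nm], class_sd = class_sd[nm],
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# draw tail + background percent changes for one ancestry, guaranteeing the
# tail invariants: every high value below every low value, background strictly
# in between.  At default parameters the redraw loop is hit with probability
# ~1e-8, so class means are unbiased for practical purposes.
draw_ancestry_pct <- function(n_high, n_low, n_none, mean_high, sd_high,
                              mean_low, sd_low) {
  repeat {
    high <- stats::rnorm(n_high, mean_high, sd_high)
    low <- stats::rnorm(n_low, mean_low, sd_low)
    if (max(high) < min(low)) break
  }
  none <- if (n_none > 0) stats::runif(n_none, max(high), min(low)) else numeric(0)
  list(high = high, low = low, none = none)
}

#' Simulate a two-ancestry statin-response cohort
#'
#' Generates one phenotype record per sample: tail-selected high and low LDLC
#' responders in both ancestries (plus non-tail EA background samples),
#' delta-log clinical lipid phenotypes, and covariates (age, sex, smoking,
#' experiment batch) whose latent liabilities are correlated with the hidden
#' confounding factors that later drive the expression simulation.  The
#' confounder factor scores are attached as the `"confounders"` attribute so
#' [simulate_expression()] sees the same latent structure.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per sample (columns `sample_id`, `ancestry`,
#'   `responder_class`, `pct_change_ldlc`, `delta_log_ldlc`, `delta_log_tc`,
#'   `delta_log_tg`, `delta_log_hdlc`, `age`, `sex`, `smoker`, `batch`), with
#'   the latent confounder score matrix in `attr(, "confounders")`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cm <- config$class_mean; cs <- config$class_sd
  with_seed(config$seed + 1L, {
    ea <- draw_ancestry_pct(config$n_ea_high, config$n_ea_low,
                            config$n_background_samples,
                            cm[["ea_high"]], cs[["ea_high"]],
                            cm[["ea_low"]], cs[["ea_low"]])
    aa <- draw_ancestry_pct(config$n_aa_high, config$n_aa_low, 0,
                            cm[["aa_high"]], cs[["aa_high"]],
                            cm[["aa_low"]], cs[["aa_low"]])
    n_ea <- config$n_ea_high + config$n_ea_low + config$n_background_samples
    n_aa <- config$n_aa_high + config$n_aa_low
    n <- n_ea + n_aa
    tab <- tibble::tibble(
      sample_id = c(sprintf("EA%03d", seq_len(n_ea)),
                    sprintf("AA%03d", seq_len(n_aa))),
      ancestry = rep(c("EA", "AA"), c(n_ea, n_aa)),
      responder_class = c(rep(c("high", "low", "none"),
                              c(config$n_ea_high, config$n_ea_low,
                                config$n_background_samples)),
                          rep(c("high", "low"),
                              c(config$n_aa_high, config$n_aa_low))),
      pct_change_ldlc = c(ea$high, ea$low, ea$none, aa$high, aa$low)
    )
    # latent confounders: one standard-normal factor score per (sample, k)
    k <- config$n_confounders
    f <- matrix(stats::rnorm(n * max(k, 1L)), nrow = n)
    if (k == 0) f <- f[, 0, drop = FALSE]
    rownames(f) <- tab$sample_id
    if (k > 0) colnames(f) <- paste0("f", seq_len(k))
    # measured covariates share a latent liability with confounder 1, 2, 3
    # (cycled) at correlation `covariate_confounder_corr`
    rho <- config$covariate_confounder_corr
    liability <- function(j) {
      base <- if (k > 0) f[, ((j - 1L) %% k) + 1L] else rep(0, n)
      rho * base + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    tab$age <- pmin(75, pmax(30, round(53 + 11 * liability(1))))
    tab$sex <- ifelse(liability(2) > 0, "M", "F")
    tab$smoker <- ifelse(liability(3) > stats::qnorm(0.9), "yes", "no")
    tab$batch <- ifelse(liability(1) > 0, "batch1", "batch2")
    # continuous lipid responses on the delta-log scale
    tab$delta_log_ldlc <- log1p(tab$pct_change_ldlc / 100)
    tab$delta_log_tc <- 0.35 * tab$delta_log_ldlc + stats::rnorm(n, 0, 0.08)
    tab$delta_log_tg <- stats::rnorm(n, 0, 0.20)
    tab$delta_log_hdlc <- stats::rnorm(n, 0, 0.10)
    tab <- tab[, c("sample_id", "ancestry", "responder_class",
                   "pct_change_ldlc", "delta_log_ldlc", "delta_log_tc",
                   "delta_log_tg", "delta_log_hdlc", "age", "sex", "smoker",
                   "batch")]
    attr(tab, "confounders") <- f
    tab
  })
}

#' Label the tails of an ancestry's LDLC-response distribution
#'
#' Relabels `responder_class` within one ancestry: the `n_high` most negative
#' `pct_change_ldlc` samples (strongest LDLC reduction) become `"high"`, the
#' `n_low` least negative become `"low"`, everything else in that ancestry
#' becomes `"none"`.  Boundary ties are broken by lexicographic `sample_id`.
#'
#' @param phenotypes Phenotype tibble with `sample_id`, `ancestry`,
#'   `pct_change_ldlc`.
#' @param n_high,n_low Tail sizes.
#' @param ancestry Which ancestry to relabel.
#' @return The phenotype tibble with `responder_class` updated.
#' @export
label_tails <- function(phenotypes, n_high, n_low, ancestry) {
  stopifnot(is.data.frame(phenotypes),
            all(c("sample_id", "ancestry", "pct_change_ldlc") %in%
                  names(phenotypes)))
  sel <- phenotypes$ancestry == ancestry & is.finite(phenotypes$pct_change_ldlc)
  if (sum(sel) < n_high + n_low) {
    stop(sprintf("ancestry %s has %d usable samples; need %d", ancestry,
                 sum(sel), n_high + n_low), call. = FALSE)
  }
  idx <- which(sel)
  ord <- idx[order(phenotypes$pct_change_ldlc[idx], phenotypes$sample_id[idx])]
  cls <- rep("none", length(ord))
  cls[seq_len(n_high)] <- "high"
  cls[seq(length(ord) - n_low + 1L, length(ord))] <- "low"
  if (!"responder_class" %in% names(phenotypes)) phenotypes$responder_class <- "none"
  phenotypes$responder_class[ord] <- cls
  phenotypes
}

#' Simulate paired control/statin expression matrices
#'
#' Draws a control matrix (per-gene baselines plus noise) and a statin matrix
#' whose difference follows the generative model
#' `delta_gi = beta_g z_i + sum_k lambda_gk f_ki + b_batch(i),g + eps_gi`:
#' `z` is +1 for high responders, -1 for low, 0 otherwise; `beta_g` is
#' `+/- effect_size / 2` at the planted signature genes (sign fixed per gene
#' and shared across ancestries) and 0 elsewhere; `f` are the cohort's latent
#' confounder scores; `b` a per-gene batch offset; `eps` Gaussian noise.
#'
#' @param cohort Phenotype tibble from [simulate_cohort()] (or any table with
#'   `sample_id`, `ancestry`, `responder_class`, `batch`).
#' @param config A [simulation_config()].
#' @return A list of class `paired_expression`: `control` and `statin`
#'   (genes x samples matrices), `planted_genes`, `planted_signs`, and
#'   `ce_gene` (the designated cholesterol-ester-coupled signature gene,
#'   always planted with positive sign so high responders show the larger
#'   expression increase).
#' @export
simulate_expression <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(cohort),
            nrow(cohort) > 0)
  ea <- cohort[cohort$ancestry == "EA", ]
  if (!all(c("high", "low") %in% ea$responder_class)) {
    stop("discovery (EA) cohort must contain both high and low responders",
         call. = FALSE)
  }
  n <- nrow(cohort)
  g <- config$n_genes
  genes <- sprintf("g%05d", seq_len(g))
  f <- attr(cohort, "confounders")
  with_seed(config$seed + 2L, {
    if (is.null(f)) {
      f <- matrix(stats::rnorm(n * config$n_confounders), nrow = n)
    }
    f <- f[, seq_len(min(ncol(f), config$n_confounders)), drop = FALSE]
    planted_idx <- sort(sample.int(g, config$n_signature))
    signs <- sample(c(-1, 1), config$n_signature, replace = TRUE)
    signs[1L] <- 1  # designated CE-coupled gene responds upward in high responders
    beta <- numeric(g)
    beta[planted_idx] <- signs * config$effect_size / 2
    z <- ifelse(cohort$responder_class == "high", 1,
                ifelse(cohort$responder_class == "low", -1, 0))
    lambda <- matrix(stats::rnorm(g * ncol(f), 0, config$confounder_loading_sd),
                     nrow = g)
    batch <- factor(cohort$batch)
    b <- matrix(stats::rnorm(g * nlevels(batch), 0, config$batch_effect_sd),
                nrow = g)
    eps <- matrix(stats::rnorm(g * n, 0, config$noise_sd), nrow = g)
    biological <- tcrossprod(beta, z) + eps
    delta <- biological +
      (if (ncol(f) > 0) tcrossprod(lambda, f) else 0) +
      b[, as.integer(batch), drop = FALSE]
    baseline <- stats::rnorm(g, 8, 2)
    control <- baseline + matrix(stats::rnorm(g * n, 0, config$noise_sd),
                                 nrow = g)
    statin <- control + delta
    dimnames(control) <- dimnames(statin) <- list(genes, cohort$sample_id)
    ce_idx <- planted_idx[1L]
    structure(
      list(control = control, statin = statin,
           planted_genes = genes[planted_idx],
           planted_signs = stats::setNames(signs, genes[planted_idx]),
           ce_gene = genes[ce_idx],
           # the designated gene's biological statin response (class effect +
           # biological noise, free of technical confounders and batch): the
           # component the cholesterol phenotype couples to
           ce_gene_delta = stats::setNames(biological[ce_idx, ],
                                           cohort$sample_id)),
      class = "paired_expression"
    )
  })
}

#' @export
print.paired_expression <- function(x, ...) {
  cat(sprintf("<paired_expression> %d genes x %d samples; %d planted (CE-coupled: %s)\n",
              nrow(x$control), ncol(x$control), length(x$planted_genes),
              x$ce_gene))
  invisible(x)
}

#' Simulate cellular cholesterol phenotypes coupled to one signature gene
#'
#' The cholesterol-ester delta is `ce_coupling * standardized(planted gene
#' delta) + responder-class offset + noise` (high responders shifted down:
#' stronger LDLC response goes with a larger statin-induced depletion of
#' stored cholesterol ester); the free-cholesterol delta is pure noise,
#' providing a negative control.
#'
#' @param cohort Phenotype tibble.
#' @param planted_gene_delta Numeric vector of the designated gene's delta
#'   expression, aligned with `cohort` rows.
#' @param config A [simulation_config()].
#' @return `cohort` with `ce_delta` and `fc_delta` columns added.
#' @export
simulate_cholesterol <- function(cohort, planted_gene_delta, config) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(cohort))
  if (length(planted_gene_delta) != nrow(cohort)) {
    stop("planted_gene_delta must align with cohort rows (",
         length(planted_gene_delta), " vs ", nrow(cohort), ")", call. = FALSE)
  }
  gs <- as.numeric(scale(planted_gene_delta))
  if (any(!is.finite(gs))) gs <- rep(0, nrow(cohort))  # constant input
  offset <- ifelse(cohort$responder_class == "high", -config$ce_class_offset,
                   ifelse(cohort$responder_class == "low",
                          config$ce_class_offset, 0))
  with_seed(config$seed + 3L, {
    cohort$ce_delta <- config$ce_coupling * gs + offset +
      stats::rnorm(nrow(cohort), 0, config$ce_noise_sd)
    cohort$fc_delta <- stats::rnorm(nrow(cohort), 0, config$ce_noise_sd)
  })
  cohort
}

#' Simulate a complete study: cohort, expression pair, cholesterol phenotypes
#'
#' Convenience wrapper chaining [simulate_cohort()], [simulate_expression()]
#' and [simulate_cholesterol()] (the latter driven by the designated gene's
#' biological statin response, i.e. its delta free of technical confounder
#' and batch components — a lab-measured lipid phenotype shares the gene's
#' biology, not the expression assay's technical structure).
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_study`: `cohort` (with `ce_delta`,
#'   `fc_delta`), `control`, `statin`, `planted_genes`, `planted_signs`,
#'   `ce_gene`, `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  cohort <- simulate_cohort(config)
  expr <- simulate_expression(cohort, config)
  cohort <- simulate_cholesterol(cohort, expr$ce_gene_delta[cohort$sample_id],
                                 config)
  structure(
    list(cohort = cohort, control = expr$control, statin = expr$statin,
         planted_genes = expr$planted_genes,
         planted_signs = expr$planted_signs, ce_gene = expr$ce_gene,
         ce_gene_delta = expr$ce_gene_delta, config = config),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d genes x %d samples (%d EA / %d AA), %d planted genes\n",
              nrow(x$control), ncol(x$control),
              sum(x$cohort$ancestry == "EA"), sum(x$cohort$ancestry == "AA"),
              length(x$planted_genes)))
  invisible(x)
}

# per-sample class labels (high/low/none) named by sample id, for one ancestry
responder_labels <- function(cohort, ancestry) {
  sub <- cohort[cohort$ancestry == ancestry, ]
  stats::setNames(sub$responder_class, sub$sample_id)
}
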