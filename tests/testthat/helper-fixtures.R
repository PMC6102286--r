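# small study configurations and seeded matrices shared across test files

tiny_config <- function(...) {
  simulation_config(n_genes = 200L, n_signature = 10L,
                    n_background_samples = 10L, ...)
}

# seeded random matrix with gene/sample dimnames
rand_matrix <- function(n_genes, n_samples, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, sd = sd), nrow = n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    m
  })
}

# balanced high/low labels named by the columns of a matrix
split_labels <- function(m, n_high = floor(ncol(m) / 2)) {
  ids <- colnames(m)
  stats::setNames(rep(c("high", "low"),
                      c(n_high, length(ids) - n_high)), ids)
}

# quantile-normalized, batch-adjusted delta plus discovery/validation labels
# for one simulated study
prepared_study <- function(config) {
  st <- simulate_study(config)
  d <- compute_delta(st$statin, st$control)
  d <- quantile_normalize(d)
  d <- regress_out_batch(d, stats::setNames(st$cohort$batch,
                                            st$cohort$sample_id))
  list(study = st, delta = d, pca = pca_samples(d),
       disc = responder_labels_for(st$cohort, "EA"),
       val = responder_labels_for(st$cohort, "AA"))
}

responder_labels_for <- function(cohort, ancestry) {
  sub <- cohort[cohort$ancestry == ancestry, ]
  stats::setNames(sub$responder_class, sub$sample_id)
}
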