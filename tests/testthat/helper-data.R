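# Shared builders for small synthetic inputs.

# A tiny deterministic expression matrix with named genes/samples.
tiny_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# Balanced five-class cohort with planted markers; fast defaults.
quick_sim <- function(n = 20, delta = 3, sigma = 0.5, n_noise = 5, seed = 1,
                      include_normal_like = TRUE,
                      normal_like_delta = delta, n_normal = n) {
  cfg <- sim_config(
    n_per_class = stats::setNames(c(n, n, n, n, n_normal), subtype_levels()),
    markers = default_markers(delta = delta,
                              include_normal_like = include_normal_like,
                              normal_like_delta = normal_like_delta),
    n_noise_genes = n_noise, sigma = sigma, seed = seed
  )
  simulate_subtypes(cfg)
}

# One-gene matrix holding two groups as LumA vs LumB, for rank-sum tests.
two_group_mat <- function(a, b, gene = "G1") {
  n <- length(a) + length(b)
  mat <- matrix(c(a, b), nrow = 1,
                dimnames = list(gene, sprintf("s%02d", seq_len(n))))
  labels <- tibble::tibble(
    sample_id = colnames(mat),
    subtype = rep(c("LumA", "LumB"), c(length(a), length(b)))
  )
  list(mat = mat, labels = labels)
}

# Arguments that keep cv_train() fast in unit tests.
fast_cv <- list(folds = 3, repeats = 1, tune_grid_size = 1, ntree = 100)

fast_cv_train <- function(features, labels, algorithm = "rf", seed = 1) {
  cv_train(features, labels, algorithm = algorithm,
           folds = fast_cv$folds, repeats = fast_cv$repeats,
           tune_grid_size = fast_cv$tune_grid_size, seed = seed,
           ntree = fast_cv$ntree)
}
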