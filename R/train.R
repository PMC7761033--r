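# Learner registry -----------------------------------------------------------
#
# Four learners behind one interface. Feature columns are renamed to safe
# names (f1..fp) before fitting because pair names like "ESR1/ERBB2" are not
# syntactic; the public feature names live in the model object and are
# checked against new data at prediction time.

.algorithms <- c("rf", "svm", "cart", "nb")

.algo_label <- c(rf = "random forest", svm = "SVM (radial kernel)",
                 cart = "CART", nb = "naive Bayes")

.safe_names <- function(p) paste0("f", seq_len(p))

# `size` grid points centred on the learner's customary default (a single
# point collapses to that default). The naive Bayes learner has no effective
# tunable parameter for continuous features (Gaussian likelihoods), so its
# grid has a single row.
.grid_seq <- function(from, to, size) {
  if (size == 1L) (from + to) / 2 else seq(from, to, length.out = size)
}

.tune_grid <- function(algorithm, p, size) {
  switch(algorithm,
    rf = tibble(mtry = unique(pmax(1L, pmin(p,
      round(sqrt(p) * 2^.grid_seq(-1, 1, size)))))),
    svm = tidyr::expand_grid(
      cost = 2^.grid_seq(-1, 3, size),
      gamma = (1 / p) * 2^.grid_seq(-1, 1, size)
    ),
    cart = tibble(cp = 10^.grid_seq(-3, -1, size)),
    nb = tibble(laplace = 0),
    abort(sprintf("Unknown algorithm `%s`.", algorithm))
  )
}

.fit_learner <- function(algorithm, x, y, params, ntree = 500) {
  df <- as.data.frame(x)
  names(df) <- .safe_names(ncol(x))
  switch(algorithm,
    rf = randomForest::randomForest(
      x = df, y = y, mtry = params$mtry, ntree = ntree, importance = FALSE
    ),
    svm = e1071::svm(
      x = df, y = y, kernel = "radial",
      cost = params$cost, gamma = params$gamma, probability = FALSE
    ),
    cart = rpart::rpart(
      y ~ ., data = cbind(y = y, df), method = "class",
      control = rpart::rpart.control(cp = params$cp, xval = 0)
    ),
    nb = e1071::naiveBayes(x = df, y = y, laplace = params$laplace)
  )
}

.predict_learner <- function(algorithm, fit, x) {
  df <- as.data.frame(x)
  names(df) <- .safe_names(ncol(x))
  out <- switch(algorithm,
    rf = predict(fit, newdata = df, type = "response"),
    svm = predict(fit, newdata = df),
    cart = predict(fit, newdata = df, type = "class"),
    nb = predict(fit, newdata = df, type = "class")
  )
  factor(as.character(out), levels = subtype_levels())
}

# Stratified fold assignment: integer vector of fold ids, balanced per class.
.stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cl in levels(droplevels(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

# Split/merge helpers --------------------------------------------------------

#' Stratified train/test split of an expression cohort
#'
#' Splits samples into a training and a test part while preserving the
#' per-subtype proportions to within rounding, reproducibly for a given seed.
#'
#' @param mat Linear-scale genes-by-samples matrix.
#' @param labels Label table covering all samples; every class needs at least
#'   2 samples.
#' @param ratio Fraction of each class assigned to the training part
#'   (default 0.8, i.e. a 4:1 split); must leave a non-empty test part.
#' @param seed Integer seed controlling the random assignment.
#' @return List with elements `train` and `test`, each a list holding `mat`
#'   and `labels` for that part.
#' @export
split_train_test <- function(mat, labels, ratio = 0.8, seed = 1) {
  .check_expression(mat)
  y <- .label_factor(labels, colnames(mat))
  .assert_scalar_number(ratio, "ratio", lower = 0)
  if (ratio <= 0 || ratio >= 1) {
    abort("`ratio` must lie strictly between 0 and 1 (both parts non-empty).")
  }
  sizes <- table(droplevels(y))
  if (any(sizes < 2L)) {
    abort(sprintf("Subtype(s) with < 2 samples: %s.",
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(levels(droplevels(y)), function(cl) {
      idx <- which(y == cl)
      n_train <- min(max(1L, round(ratio * length(idx))), length(idx) - 1L)
      sort(sample(idx, n_train))
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  part <- function(idx) {
    list(mat = mat[, idx, drop = FALSE],
         labels = tibble(sample_id = colnames(mat)[idx],
                         subtype = as.character(y[idx])))
  }
  list(train = part(train_idx), test = part(test_idx))
}

# Cross-validated training ---------------------------------------------------

#' Train one classifier by repeated stratified cross-validation
#'
#' Runs `repeats` rounds of stratified `folds`-fold cross-validation over an
#' automatic hyperparameter grid (`tune_grid_size` values per tunable
#' parameter), scores each hyperparameter combination by its mean held-out
#' accuracy, and refits the best combination on all supplied samples. All
#' randomness (fold assignment, learner fitting) derives from `seed`, so the
#' result is reproducible bit-for-bit.
#'
#' @param features A `"pger_features"` samples-by-pairs matrix.
#' @param labels Label table covering the feature rows.
#' @param algorithm One of `"rf"` (random forest), `"svm"` (radial-kernel
#'   SVM), `"cart"` (classification tree), `"nb"` (naive Bayes).
#' @param folds Number of CV folds (default 5); every class needs at least
#'   `folds` samples.
#' @param repeats Number of CV repetitions (default 10; raise to 100 for a
#'   full-scale run).
#' @param tune_grid_size Grid points per tunable hyperparameter (default 3).
#' @param seed Integer seed.
#' @param ntree Trees per random forest (ignored by other learners).
#' @return An object of class `"miniabs_model"`: the refit classifier plus
#'   `cv_accuracy`, the per-combination CV table, the gene set, the slack
#'   margin, and the resolved configuration.
#' @export
cv_train <- function(features, labels, algorithm = "rf", folds = 5,
                     repeats = 10, tune_grid_size = 3, seed = 1, ntree = 500) {
  algorithm <- match.arg(algorithm, .algorithms)
  x <- unclass(features)
  if (!is.matrix(x) || is.null(rownames(x))) {
    abort("`features` must be a samples-by-pairs matrix with sample rownames.")
  }
  y <- .label_factor(labels, rownames(x))
  y <- droplevels(y)
  sizes <- table(y)
  if (any(sizes < folds)) {
    abort(sprintf("Subtype(s) with fewer than %d samples (one per fold): %s.",
                  folds, paste(names(sizes)[sizes < folds], collapse = ", ")))
  }
  grid <- .tune_grid(algorithm, ncol(x), tune_grid_size)

  # Held-out accuracy for every (repeat, fold, grid row); fold layouts and
  # each fit get deterministic seeds derived from `seed`.
  acc <- matrix(NA_real_, nrow = repeats * folds, ncol = nrow(grid))
  row <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_id <- withr::with_seed(seed + 7919L * rep_i,
                                .stratified_folds(y, folds))
    for (fold_i in seq_len(folds)) {
      row <- row + 1L
      hold <- fold_id == fold_i
      if (length(unique(y[!hold])) < 2L) {
        abort("Degenerate fold: training part holds a single class.")
      }
      for (g in seq_len(nrow(grid))) {
        fit <- withr::with_seed(
          seed + 104729L * rep_i + 1299709L * fold_i + g,
          .fit_learner(algorithm, x[!hold, , drop = FALSE], y[!hold],
                       grid[g, ], ntree = ntree)
        )
        pred <- .predict_learner(algorithm, fit, x[hold, , drop = FALSE])
        acc[row, g] <- mean(as.character(pred) == as.character(y[hold]))
      }
    }
  }
  grid$cv_accuracy <- colMeans(acc)
  best <- which.max(grid$cv_accuracy)
  final <- withr::with_seed(seed + 15485863L,
                            .fit_learner(algorithm, x, y, grid[best, ],
                                         ntree = ntree))
  structure(
    list(
      algorithm = algorithm,
      alpha = attr(features, "alpha") %||% NA_real_,
      genes = as.character(attr(features, "genes")),
      feature_names = colnames(x),
      fit = final,
      cv_accuracy = grid$cv_accuracy[best],
      best_params = as.list(grid[best, setdiff(names(grid), "cv_accuracy")]),
      cv_results = tibble::as_tibble(grid),
      folds = folds, repeats = repeats, tune_grid_size = tune_grid_size,
      ntree = ntree, seed = seed,
      classes = levels(y)
    ),
    class = "miniabs_model"
  )
}

#' @export
print.miniabs_model <- function(x, ...) {
  cat(sprintf(
    "<miniabs_model> %s | alpha = %.2f | %d genes, %d PGER features\n",
    .algo_label[[x$algorithm]], x$alpha, length(x$genes),
    length(x$feature_names)
  ))
  cat(sprintf("  CV accuracy %.4f (%d-fold x %d repeats)\n",
              x$cv_accuracy, x$folds, x$repeats))
  invisible(x)
}

# Predict subtype votes of a single trained model on a feature matrix.
.predict_model <- function(model, features) {
  x <- unclass(features)
  if (!identical(colnames(x), model$feature_names)) {
    abort("Feature columns do not match the model's training features.")
  }
  .predict_learner(model$algorithm, model$fit, x)
}

#' Predict with a single cross-validated model
#'
#' @param object A `"miniabs_model"`.
#' @param mat Linear-scale genes-by-samples matrix containing the model's
#'   genes (features are rebuilt at the model's slack margin).
#' @param ... Unused.
#' @return Tibble with `sample_id` and `subtype` (the predicted class).
#' @export
predict.miniabs_model <- function(object, mat, ...) {
  feats <- feature_matrix(mat, object$genes, alpha = object$alpha)
  tibble(sample_id = rownames(feats),
         subtype = as.character(.predict_model(object, feats)))
}

# Grid training --------------------------------------------------------------

#' Train the full (level, algorithm, alpha) configuration grid
#'
#' For each gene-set level, each learning algorithm and each slack margin,
#' builds the PGER feature matrix and trains a cross-validated model. One
#' level with the default 4 algorithms and 7 slack margins yields 28
#' configurations.
#'
#' @param mat Linear-scale genes-by-samples matrix (training cohort).
#' @param labels Label table.
#' @param ssdeg_table Ranked subtype-specific gene table supporting the
#'   deepest requested level.
#' @param seeds Seed genes prepended to every gene set; pass `character(0)`
#'   for the ssDEG-only ablation. Pass `levels = 0` (with seeds) for the
#'   seeds-only ablation.
#' @param levels Integer vector of gene-set levels (default `1:5`).
#' @param algorithms Subset of `c("rf", "svm", "cart", "nb")`.
#' @param alphas Slack margin values (default [alpha_grid()]).
#' @param folds,repeats,tune_grid_size,ntree Passed to [cv_train()].
#' @param seed Integer seed; each configuration trains with a distinct seed
#'   derived from it.
#' @return A tibble of class `"miniabs_grid"` with one row per configuration:
#'   `level`, `n_genes`, `algorithm`, `alpha`, `cv_accuracy` and a `model`
#'   list-column holding the trained `"miniabs_model"` objects.
#' @export
run_grid <- function(mat, labels, ssdeg_table, seeds = seed_genes(),
                     levels = 1:5, algorithms = .algorithms,
                     alphas = alpha_grid(), folds = 5, repeats = 10,
                     tune_grid_size = 3, seed = 1, ntree = 500) {
  if (!length(algorithms)) abort("`algorithms` must not be empty.")
  if (!length(alphas)) abort("`alphas` must not be empty.")
  if (!length(levels)) abort("`levels` must not be empty.")
  algorithms <- unname(vapply(algorithms, match.arg, character(1),
                              choices = .algorithms))
  configs <- tidyr::expand_grid(level = sort(unique(levels)),
                                algorithm = algorithms, alpha = alphas)
  configs$config <- seq_len(nrow(configs))
  rows <- purrr::pmap(configs, function(level, algorithm, alpha, config) {
    genes <- build_gene_set(seeds, ssdeg_table, k = level)
    feats <- feature_matrix(mat, genes, alpha = alpha)
    cfg_seed <- seed + config
    model <- cv_train(feats, labels, algorithm = algorithm, folds = folds,
                      repeats = repeats, tune_grid_size = tune_grid_size,
                      seed = cfg_seed, ntree = ntree)
    tibble(level = level, n_genes = length(genes), algorithm = algorithm,
           alpha = alpha, cv_accuracy = model$cv_accuracy,
           model = list(model))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("miniabs_grid", class(out))
  out
}

#' Select the initial model from a configuration grid
#'
#' Picks the smallest gene-set level whose best cross-validation accuracy is
#' within `tolerance` of the grid-wide best, honouring the principle that the
#' classifier with the smallest gene set but (near-)maximal classification
#' power wins. Within the chosen level, accuracy ties are broken by a fixed
#' algorithm preference (rf, svm, cart, nb), then by the smaller slack
#' margin.
#'
#' @param grid A `"miniabs_grid"` tibble from [run_grid()] (the `model`
#'   column is optional; selection uses only `level`, `algorithm`, `alpha`,
#'   `cv_accuracy`).
#' @param tolerance Absolute accuracy slack for preferring a smaller gene
#'   set (default 0.005).
#' @return List with `level` (the chosen level), `row` (the winning grid row
#'   as a one-row tibble) and `model` (the trained model, or `NULL` if the
#'   grid carries no model column).
#' @export
select_initial_model <- function(grid, tolerance = 0.005) {
  if (!is.data.frame(grid) || !nrow(grid)) abort("`grid` must be a non-empty grid table.")
  .assert_scalar_number(tolerance, "tolerance", lower = 0)
  by_level <- dplyr::summarise(dplyr::group_by(grid, .data$level),
                               best = max(.data$cv_accuracy), .groups = "drop")
  global_best <- max(by_level$best)
  k_star <- min(by_level$level[by_level$best >= global_best - tolerance])
  cand <- dplyr::filter(grid, .data$level == k_star)
  cand <- cand[order(-cand$cv_accuracy, match(cand$algorithm, .algorithms),
                     cand$alpha), ]
  row <- cand[1L, ]
  list(
    level = k_star,
    row = tibble::as_tibble(row[setdiff(names(row), "model")]),
    model = if ("model" %in% names(row)) row$model[[1L]] else NULL
  )
}
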