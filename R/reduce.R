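#' Gini-importance ranking of panel genes
#'
#' Reads the mean-decrease-in-Gini importance of every PGER feature from a
#' fitted random forest and aggregates it to the gene level: a gene's score
#' is the sum of the importances of the n-1 pair features it appears in, so a
#' gene informative in many pairings scores high. Genes are ranked by
#' descending score, ties broken by gene symbol. Mean aggregation is
#' available for comparison.
#'
#' @param model A `"miniabs_model"` trained with `algorithm = "rf"` (the only
#'   learner exposing per-feature Gini importances).
#' @param aggregate `"sum"` (default) or `"mean"` over incident pair
#'   features.
#' @return An object of class `"miniabs_importance"`: list with `genes`
#'   (tibble `gene`, `importance`, `rank`) and `features` (tibble `feature`,
#'   `importance`).
#' @export
gene_importance <- function(model, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(model, "miniabs_model") || model$algorithm != "rf") {
    abort("Gini importances require a random forest model (`algorithm = \"rf\"`).")
  }
  imp <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
  features <- tibble(feature = model$feature_names,
                     importance = unname(imp))
  pair <- strsplit(features$feature, "/", fixed = TRUE)
  long <- tibble(
    gene = unlist(pair),
    importance = rep(features$importance, lengths(pair))
  )
  agg_fun <- if (aggregate == "sum") sum else mean
  genes <- dplyr::summarise(dplyr::group_by(long, .data$gene),
                            importance = agg_fun(.data$importance),
                            .groups = "drop")
  genes <- dplyr::arrange(genes, dplyr::desc(.data$importance), .data$gene)
  genes$rank <- seq_len(nrow(genes))
  structure(list(genes = genes, features = features, aggregate = aggregate),
            class = "miniabs_importance")
}

#' @export
print.miniabs_importance <- function(x, ...) {
  cat(sprintf("<miniabs_importance> %d genes (%s over incident pairs)\n",
              nrow(x$genes), x$aggregate))
  print(x$genes, n = nrow(x$genes))
  invisible(x)
}

#' Locate the informative/uninformative gap in a gene importance ranking
#'
#' Finds the position of the largest consecutive drop in the
#' descending-sorted gene importance sequence. Genes at or above that
#' position form the highly informative group that stepwise reduction must
#' never remove.
#'
#' @param importance A `"miniabs_importance"` object, or a numeric vector of
#'   gene scores.
#' @return Integer: the number of protected (highly informative) genes.
#' @export
detect_importance_gap <- function(importance) {
  scores <- if (inherits(importance, "miniabs_importance")) {
    importance$genes$importance
  } else {
    as.numeric(importance)
  }
  if (length(scores) < 3L) abort("Need at least 3 genes to locate a gap.")
  scores <- sort(scores, decreasing = TRUE)
  drops <- scores[-length(scores)] - scores[-1L]
  which.max(drops) # first position on exact ties
}

#' Stepwise Gini-guided reduction of the candidate gene set
#'
#' Starting from an initial trained model, removes the currently
#' lowest-ranked unprotected gene (by the initial Gini ranking), rebuilds the
#' PGER features and retrains with the identical algorithm, slack margin and
#' CV protocol, recording each accuracy. Removal stops when accuracy falls
#' more than `drop_tolerance` below the running best, or when only protected
#' genes remain. Among the initial model and all retrained reductions whose
#' accuracy is within `drop_tolerance` of the best observed, the model with
#' the fewest genes is returned (higher accuracy breaks ties) — accuracy
#' parity is spent on panel size, which is the point of the reduction.
#'
#' @param initial A trained `"miniabs_model"` (random forest for the default
#'   importance ranking).
#' @param mat Linear-scale genes-by-samples training matrix.
#' @param labels Label table.
#' @param importance Optional precomputed `"miniabs_importance"`; computed
#'   from `initial` when `NULL`.
#' @param protected_count Number of top-ranked genes never removed; detected
#'   with [detect_importance_gap()] when `NULL`.
#' @param drop_tolerance Accuracy slack (default 0.005) for both the stopping
#'   rule and the final fewest-genes choice.
#' @param rerank Recompute the importance ranking after each removal
#'   (default `FALSE`: the initial ranking fixes the removal order).
#' @param seed Integer seed for the retraining runs.
#' @param retrain Retraining hook: `function(genes, step)` returning a list
#'   with at least `cv_accuracy` and optionally `model`. The default rebuilds
#'   features and calls [cv_train()] with the initial model's configuration;
#'   the hook exists so reduction logic can be exercised against scripted
#'   accuracies.
#' @return An object of class `"miniabs_reduction"`: list with `model` (the
#'   selected model), `genes`, `path` (tibble of every candidate: `step`,
#'   `removed_gene`, `n_genes`, `cv_accuracy`, `selected`) and
#'   `protected_count`.
#' @export
reduce_genes <- function(initial, mat = NULL, labels = NULL,
                         importance = NULL, protected_count = NULL,
                         drop_tolerance = 0.005, rerank = FALSE, seed = 1,
                         retrain = NULL) {
  if (!inherits(initial, "miniabs_model")) {
    abort("`initial` must be a trained miniabs model.")
  }
  .assert_scalar_number(drop_tolerance, "drop_tolerance", lower = 0)
  if (is.null(importance)) importance <- gene_importance(initial)
  if (is.null(protected_count)) protected_count <- detect_importance_gap(importance)
  if (protected_count >= length(initial$genes)) {
    abort("`protected_count` must be smaller than the initial gene set.")
  }
  if (is.null(retrain)) {
    if (is.null(mat) || is.null(labels)) {
      abort("Supply `mat` and `labels` (or a `retrain` hook).")
    }
    retrain <- function(genes, step) {
      feats <- feature_matrix(mat, genes, alpha = initial$alpha)
      model <- cv_train(feats, labels, algorithm = initial$algorithm,
                        folds = initial$folds, repeats = initial$repeats,
                        tune_grid_size = initial$tune_grid_size,
                        seed = seed + step, ntree = initial$ntree)
      list(model = model, cv_accuracy = model$cv_accuracy)
    }
  }

  rank_of <- function(imp) imp$genes$gene[order(imp$genes$rank)]
  ranking <- rank_of(importance)
  stray <- setdiff(initial$genes, ranking)
  if (length(stray)) {
    abort(sprintf("Importance ranking is missing gene(s): %s.",
                  paste(stray, collapse = ", ")))
  }
  protected <- ranking[seq_len(protected_count)]

  candidates <- list(list(step = 0L, removed_gene = NA_character_,
                          genes = initial$genes, model = initial,
                          cv_accuracy = initial$cv_accuracy))
  current <- initial$genes
  best_acc <- initial$cv_accuracy
  step <- 0L
  repeat {
    removable <- setdiff(ranking, protected)
    removable <- removable[removable %in% current]
    if (!length(removable)) break
    victim <- removable[length(removable)] # lowest-ranked unprotected gene
    step <- step + 1L
    current <- setdiff(current, victim)
    res <- retrain(current, step)
    candidates[[length(candidates) + 1L]] <-
      list(step = step, removed_gene = victim, genes = current,
           model = res$model %||% NULL, cv_accuracy = res$cv_accuracy)
    if (res$cv_accuracy < best_acc - drop_tolerance) break
    best_acc <- max(best_acc, res$cv_accuracy)
    if (rerank && !is.null(res$model) && length(current) > 2L) {
      ranking <- rank_of(gene_importance(res$model))
    }
  }

  path <- tibble(
    step = vapply(candidates, `[[`, integer(1), "step"),
    removed_gene = vapply(candidates, `[[`, character(1), "removed_gene"),
    n_genes = vapply(candidates, function(c) length(c$genes), integer(1)),
    cv_accuracy = vapply(candidates, `[[`, numeric(1), "cv_accuracy")
  )
  top <- max(path$cv_accuracy)
  eligible <- which(path$cv_accuracy >= top - drop_tolerance)
  pick <- eligible[order(path$n_genes[eligible],
                         -path$cv_accuracy[eligible])][1L]
  path$selected <- seq_len(nrow(path)) == pick
  structure(
    list(model = candidates[[pick]]$model, genes = candidates[[pick]]$genes,
         path = path, protected_count = as.integer(protected_count),
         drop_tolerance = drop_tolerance),
    class = "miniabs_reduction"
  )
}

#' @export
print.miniabs_reduction <- function(x, ...) {
  sel <- x$path[x$path$selected, ]
  cat(sprintf(
    "<miniabs_reduction> %d candidates tried; selected %d genes (CV accuracy %.4f)\n",
    nrow(x$path), sel$n_genes, sel$cv_accuracy
  ))
  print(x$path)
  invisible(x)
}
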