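#' Train the slack-margin ensemble over one gene panel
#'
#' Trains one cross-validated model per slack margin value on a fixed gene
#' panel (default: the shipped 11-gene panel, [miniabs_panel()]). At
#' prediction time the member models vote and the modal subtype wins; a tied
#' mode yields an `"Ambiguous"` call. No fitted weights are shipped with the
#' package — member models are always trained on the user's (or synthetic)
#' cohort.
#'
#' @param mat Linear-scale genes-by-samples training matrix.
#' @param labels Label table.
#' @param genes Gene panel shared by all members.
#' @param algorithm Learner for every member (default `"rf"`).
#' @param alphas Distinct slack margins, one member per value (default
#'   [alpha_grid()]).
#' @param folds,repeats,tune_grid_size,ntree,seed Passed to [cv_train()]
#'   (each member trains with a distinct seed derived from `seed`).
#' @return An object of class `"miniabs_ensemble"`.
#' @export
train_ensemble <- function(mat, labels, genes = miniabs_panel(),
                           algorithm = "rf", alphas = alpha_grid(),
                           folds = 5, repeats = 10, tune_grid_size = 3,
                           seed = 1, ntree = 500) {
  alphas <- sort(unique(as.numeric(alphas)))
  if (!length(alphas)) abort("`alphas` must not be empty.")
  models <- lapply(seq_along(alphas), function(i) {
    feats <- feature_matrix(mat, genes, alpha = alphas[i])
    cv_train(feats, labels, algorithm = algorithm, folds = folds,
             repeats = repeats, tune_grid_size = tune_grid_size,
             seed = seed + 31L * i, ntree = ntree)
  })
  names(models) <- formatC(alphas, format = "f", digits = 2)
  structure(
    list(genes = as.character(genes), algorithm = algorithm, alphas = alphas,
         models = models, seed = seed,
         meta = list(format_version = "1.0",
                     trained = format(Sys.time(), "%Y-%m-%d"))),
    class = "miniabs_ensemble"
  )
}

#' @export
print.miniabs_ensemble <- function(x, ...) {
  cat(sprintf(
    "<miniabs_ensemble> %d x %s members over %d genes (alphas: %s)\n",
    length(x$models), .algo_label[[x$algorithm]], length(x$genes),
    paste(formatC(x$alphas, format = "f", digits = 2), collapse = ", ")
  ))
  cat(sprintf("  member CV accuracies: %s\n",
              paste(sprintf("%.3f", vapply(x$models, `[[`, numeric(1),
                                           "cv_accuracy")), collapse = ", ")))
  invisible(x)
}

# Final call from a samples x members matrix of subtype votes: the unique
# modal subtype, or "Ambiguous" when the modal count is shared.
.final_call <- function(votes) {
  apply(votes, 1L, function(v) {
    counts <- table(factor(v, levels = subtype_levels()))
    top <- max(counts)
    winners <- names(counts)[counts == top]
    if (length(winners) == 1L) winners else "Ambiguous"
  })
}

#' Predict subtypes with the slack-margin ensemble
#'
#' For each member model, the sample's PGER features are rebuilt at that
#' member's slack margin and classified; the final call is the unique modal
#' subtype of the member votes, or `"Ambiguous"` on a tied mode (ambiguous
#' calls count as incorrect downstream). Every feature is computed within
#' one sample, so a sample's call is identical whether it is classified
#' alone or inside any cohort.
#'
#' @param object A `"miniabs_ensemble"`.
#' @param mat Linear-scale genes-by-samples matrix containing every panel
#'   gene.
#' @param ... Unused.
#' @return A tibble of class `"miniabs_prediction"`: `sample_id`, one
#'   `vote_<alpha>` column per member, and `final_call` (one of the five
#'   subtypes or `"Ambiguous"`).
#' @export
predict.miniabs_ensemble <- function(object, mat, ...) {
  .check_expression(mat)
  missing <- setdiff(object$genes, rownames(mat))
  if (length(missing)) {
    abort(sprintf("Panel gene(s) absent from the matrix: %s.",
                  paste(missing, collapse = ", ")))
  }
  votes <- vapply(seq_along(object$alphas), function(i) {
    feats <- feature_matrix(mat, object$genes, alpha = object$alphas[i])
    as.character(.predict_model(object$models[[i]], feats))
  }, character(ncol(mat)))
  votes <- matrix(votes, nrow = ncol(mat),
                  dimnames = list(colnames(mat),
                                  paste0("vote_", names(object$models))))
  out <- tibble::as_tibble(votes, rownames = "sample_id")
  out$final_call <- .final_call(votes)
  class(out) <- c("miniabs_prediction", class(out))
  out
}

#' Classify one standalone sample
#'
#' The single-sample entry point: classifies one expression profile given as
#' a named gene-to-value map, with no cohort context at all. The result is
#' identical to embedding the sample in any matrix and calling
#' [predict.miniabs_ensemble()].
#'
#' @param object A `"miniabs_ensemble"`.
#' @param expression Named numeric vector of linear-scale expression values
#'   covering every panel gene.
#' @param sample_id Identifier used in the output (default `"sample"`).
#' @return A one-row `"miniabs_prediction"` tibble.
#' @export
predict_single <- function(object, expression, sample_id = "sample") {
  if (!inherits(object, "miniabs_ensemble")) {
    abort("`object` must be a miniabs ensemble.")
  }
  if (!is.numeric(expression) || is.null(names(expression))) {
    abort("`expression` must be a named numeric vector (gene -> value).")
  }
  missing <- setdiff(object$genes, names(expression))
  if (length(missing)) {
    abort(sprintf("Panel gene(s) absent from the sample: %s.",
                  paste(missing, collapse = ", ")))
  }
  mat <- matrix(expression, ncol = 1L,
                dimnames = list(names(expression), sample_id))
  predict(object, mat)
}

#' Write ensemble subtype calls to TSV
#'
#' @param pred A `"miniabs_prediction"` tibble.
#' @param path Output path.
#' @export
write_predictions <- function(pred, path) {
  readr::write_tsv(pred, path)
  invisible(path)
}
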