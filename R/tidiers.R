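# broom-style accessors for the package's fitted objects

#' @method glance miniabs_model
#' @export
glance.miniabs_model <- function(x, ...) {
  tibble(algorithm = x$algorithm, alpha = x$alpha,
         n_genes = length(x$genes), n_features = length(x$feature_names),
         cv_accuracy = x$cv_accuracy, folds = x$folds, repeats = x$repeats,
         seed = x$seed)
}

#' @method tidy miniabs_model
#' @export
tidy.miniabs_model <- function(x, ...) {
  x$cv_results
}

#' @method glance miniabs_ensemble
#' @export
glance.miniabs_ensemble <- function(x, ...) {
  tibble(algorithm = x$algorithm, n_genes = length(x$genes),
         n_members = length(x$models),
         mean_cv_accuracy = mean(vapply(x$models, `[[`, numeric(1),
                                        "cv_accuracy")),
         seed = x$seed)
}

#' @method tidy miniabs_ensemble
#' @export
tidy.miniabs_ensemble <- function(x, ...) {
  tibble(alpha = x$alphas,
         cv_accuracy = vapply(x$models, `[[`, numeric(1), "cv_accuracy"))
}

#' @method tidy miniabs_importance
#' @export
tidy.miniabs_importance <- function(x, level = c("gene", "feature"), ...) {
  level <- match.arg(level)
  if (level == "gene") x$genes else x$features
}

#' @method tidy miniabs_reduction
#' @export
tidy.miniabs_reduction <- function(x, ...) {
  x$path
}

#' @method glance miniabs_reduction
#' @export
glance.miniabs_reduction <- function(x, ...) {
  sel <- x$path[x$path$selected, ]
  tibble(n_genes = sel$n_genes, cv_accuracy = sel$cv_accuracy,
         steps_tried = max(x$path$step),
         protected_count = x$protected_count)
}

#' @method tidy miniabs_eval
#' @export
tidy.miniabs_eval <- function(x, ...) {
  conf <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  names(conf) <- c("predicted", "truth", "n")
  tibble::as_tibble(conf)
}

#' @method glance miniabs_eval
#' @export
glance.miniabs_eval <- function(x, ...) {
  tibble(n_scored = x$n_scored, accuracy = x$accuracy, kappa = x$kappa,
         kappa_low = x$kappa_ci[1], kappa_high = x$kappa_ci[2],
         n_ambiguous = x$n_ambiguous,
         normal_like_excluded = x$normal_like_excluded)
}
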