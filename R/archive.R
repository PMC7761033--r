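#' Save and load a trained ensemble
#'
#' A model archive is a directory holding a plain-text, diffable
#' `manifest.json` (format version, gene panel, algorithm, slack margins,
#' per-member tuned hyperparameters, CV accuracies and seeds) plus one
#' serialized classifier per slack margin (`model_alpha_<a>.rds`).
#'
#' @param object A `"miniabs_ensemble"`.
#' @param dir Archive directory (created if needed).
#' @return `dir` (for `save_ensemble`), the restored ensemble (for
#'   `load_ensemble`).
#' @export
save_ensemble <- function(object, dir) {
  if (!inherits(object, "miniabs_ensemble")) {
    abort("`object` must be a miniabs ensemble.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  member_files <- sprintf("model_alpha_%s.rds", names(object$models))
  manifest <- list(
    format_version = object$meta$format_version %||% "1.0",
    algorithm = object$algorithm,
    panel = object$genes,
    alphas = object$alphas,
    seed = object$seed,
    members = lapply(seq_along(object$models), function(i) {
      m <- object$models[[i]]
      list(alpha = m$alpha, file = member_files[i],
           cv_accuracy = m$cv_accuracy, best_params = m$best_params,
           folds = m$folds, repeats = m$repeats, seed = m$seed,
           ntree = m$ntree)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (i in seq_along(object$models)) {
    saveRDS(object$models[[i]], file.path(dir, member_files[i]))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No manifest.json under `%s`.", dir))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  files <- if (is.data.frame(manifest$members)) {
    manifest$members$file
  } else {
    vapply(manifest$members, `[[`, character(1), "file")
  }
  models <- lapply(file.path(dir, files), readRDS)
  alphas <- vapply(models, `[[`, numeric(1), "alpha")
  names(models) <- formatC(alphas, format = "f", digits = 2)
  structure(
    list(genes = manifest$panel, algorithm = manifest$algorithm,
         alphas = alphas, models = models, seed = manifest$seed,
         meta = list(format_version = manifest$format_version)),
    class = "miniabs_ensemble"
  )
}
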