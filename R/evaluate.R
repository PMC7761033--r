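#' Cohen's kappa from a square confusion matrix
#'
#' Chance-corrected agreement between two categorical labelings, with the
#' classical asymptotic standard error
#' `se = sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` used for a 95% confidence
#' interval.
#'
#' @param confusion Square contingency matrix (rows one rater, columns the
#'   other, identical category order).
#' @return List with `kappa`, `se`, `ci` (length-2 vector, clamped to
#'   `[-1, 1]`), `p_o`, `p_e`, `n`.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    abort("`confusion` must be square (same categories on both axes).")
  }
  n <- sum(confusion)
  if (n == 0) abort("Empty confusion matrix.")
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  se <- if (p_e == 1) 0 else sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * stats::qnorm(0.975) * se))
  list(kappa = kappa, se = se, ci = ci, p_o = p_o, p_e = p_e, n = n)
}

#' Score subtype predictions against reference labels
#'
#' Computes accuracy, Cohen's kappa (with asymptotic 95% CI) and the
#' confusion matrix of final ensemble calls against reference subtype
#' labels. `"Ambiguous"` predictions always count as incorrect: they form an
#' extra prediction row of the confusion matrix with no truth column, and
#' they stay in the accuracy denominator. Because the Normal-like subtype is
#' contested (often attributed to normal-tissue contamination), scoring can
#' drop all samples whose *truth* label is Normal-like before computing any
#' statistic; the remaining confusion cells are unchanged by that drop.
#'
#' @param pred A `"miniabs_prediction"` tibble (or any data frame with
#'   `sample_id` and `final_call`).
#' @param truth Label table with `sample_id` and `subtype`; every scored
#'   sample must be labeled.
#' @param exclude_normal_like Drop samples whose truth label is Normal-like
#'   before scoring (default `FALSE`).
#' @return An object of class `"miniabs_eval"`: `n_scored`, `accuracy`,
#'   `kappa`, `kappa_se`, `kappa_ci`, `confusion` (predicted x truth
#'   matrix), `n_ambiguous`, `normal_like_excluded`.
#' @export
score <- function(pred, truth, exclude_normal_like = FALSE) {
  if (!is.data.frame(pred) || !all(c("sample_id", "final_call") %in% names(pred))) {
    abort("`pred` must have columns `sample_id` and `final_call`.")
  }
  truth <- .check_labels(truth)
  joined <- dplyr::inner_join(
    tibble(sample_id = as.character(pred$sample_id),
           final_call = as.character(pred$final_call)),
    truth, by = "sample_id"
  )
  if (!nrow(joined)) abort("No overlap between predictions and truth labels.")
  unlabeled <- setdiff(as.character(pred$sample_id), truth$sample_id)
  if (length(unlabeled)) {
    abort(sprintf("%d predicted sample(s) have no truth label (first: %s).",
                  length(unlabeled), unlabeled[1L]))
  }
  if (exclude_normal_like) {
    joined <- dplyr::filter(joined, .data$subtype != "Normal-like")
    if (!nrow(joined)) abort("All samples were Normal-like; nothing to score.")
  }
  truth_classes <- setdiff(subtype_levels(),
                           if (exclude_normal_like) "Normal-like" else character(0))
  pred_classes <- c(subtype_levels(), "Ambiguous")
  confusion <- table(
    predicted = factor(joined$final_call, levels = pred_classes),
    truth = factor(joined$subtype, levels = truth_classes)
  )
  # keep every truth class as a row; drop extra prediction-only rows
  # (Ambiguous, and Normal-like under exclusion) when they are empty
  extra <- setdiff(pred_classes, truth_classes)
  drop <- extra[rowSums(confusion[extra, , drop = FALSE]) == 0]
  confusion <- confusion[setdiff(pred_classes, drop), , drop = FALSE]
  n <- nrow(joined)
  accuracy <- mean(joined$final_call == joined$subtype)

  # kappa over the square class union; Ambiguous (if present) contributes a
  # zero truth marginal
  classes <- rownames(confusion)
  square <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  square[, colnames(confusion)] <- confusion
  kap <- cohen_kappa(square)

  structure(
    list(n_scored = n, accuracy = accuracy,
         kappa = kap$kappa, kappa_se = kap$se, kappa_ci = kap$ci,
         confusion = unclass(confusion),
         n_ambiguous = sum(joined$final_call == "Ambiguous"),
         normal_like_excluded = exclude_normal_like),
    class = "miniabs_eval"
  )
}

#' @export
print.miniabs_eval <- function(x, ...) {
  cat(sprintf(
    "<miniabs_eval> %d samples%s | accuracy %.4f | kappa %.3f (95%% CI %.3f-%.3f)\n",
    x$n_scored,
    if (x$normal_like_excluded) " (Normal-like truth excluded)" else "",
    x$accuracy, x$kappa, x$kappa_ci[1], x$kappa_ci[2]
  ))
  if (x$n_ambiguous > 0) {
    cat(sprintf("  %d ambiguous call(s), counted as incorrect\n", x$n_ambiguous))
  }
  cat("Confusion (rows = predicted, columns = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the confusion matrix as TSV (`<path>`), plus a small human-readable
#' summary block (`<path>.summary.txt`).
#'
#' @param report A `"miniabs_eval"` object.
#' @param path Output path for the confusion matrix TSV.
#' @export
write_eval_report <- function(report, path) {
  conf <- tibble::as_tibble(as.data.frame.matrix(report$confusion),
                            rownames = "predicted")
  readr::write_tsv(conf, path)
  summary_path <- paste0(path, ".summary.txt")
  writeLines(utils::capture.output(print(report)), summary_path)
  invisible(path)
}
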