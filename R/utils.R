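# internal helpers shared across modules

.assert_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower) {
    abort(sprintf("`%s` must be >= %s, got %s.", name, lower, x))
  }
  invisible(x)
}

# Validate a genes-by-samples expression matrix on the linear scale.
.check_expression <- function(mat, arg = "mat") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    abort(sprintf("`%s` must be a numeric genes-by-samples matrix.", arg))
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort(sprintf("`%s` must carry gene symbols as rownames and sample ids as colnames.", arg))
  }
  if (any(!is.finite(mat))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (any(mat < 0)) {
    abort(sprintf(
      "`%s` contains negative values; expression must be on the linear (RPKM/FPKM-like) scale. Decode log-scale input first (see read_expression()).",
      arg
    ))
  }
  invisible(mat)
}

# Coerce a label table (data.frame with sample_id, subtype) to a clean tibble.
.check_labels <- function(labels, samples = NULL) {
  if (!is.data.frame(labels) || !all(c("sample_id", "subtype") %in% names(labels))) {
    abort("`labels` must be a data frame with columns `sample_id` and `subtype`.")
  }
  labels <- tibble::as_tibble(labels[c("sample_id", "subtype")])
  labels$sample_id <- as.character(labels$sample_id)
  labels$subtype <- as.character(labels$subtype)
  if (anyDuplicated(labels$sample_id)) {
    abort("`labels` assigns some sample to more than one subtype.")
  }
  bad <- setdiff(unique(labels$subtype), subtype_levels())
  if (length(bad)) {
    abort(sprintf("Unknown subtype label(s): %s.", paste(bad, collapse = ", ")))
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, labels$sample_id)
    if (length(missing)) {
      abort(sprintf(
        "%d sample(s) have no subtype label (first few: %s).",
        length(missing), paste(head(missing, 5), collapse = ", ")
      ))
    }
    labels <- labels[match(samples, labels$sample_id), ]
  }
  labels
}

# Factor of subtype labels aligned to the given sample ids.
.label_factor <- function(labels, samples) {
  labels <- .check_labels(labels, samples)
  factor(labels$subtype, levels = subtype_levels())
}

# Pair names "Gi/Gj" for i<j in panel order, lexicographic in (i, j).
.pair_names <- function(genes) {
  if (length(genes) < 2L) {
    abort("Need at least 2 genes to form expression ratio pairs.")
  }
  idx <- utils::combn(length(genes), 2L)
  paste(genes[idx[1L, ]], genes[idx[2L, ]], sep = "/")
}
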