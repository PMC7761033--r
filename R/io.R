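#' Read a gene-by-sample expression matrix
#'
#' Reads delimited text (TSV by default, CSV for `.csv` paths) whose first
#' column holds gene or probe identifiers and whose header row holds sample
#' identifiers. Values must be non-negative linear-scale expression
#' (RPKM/FPKM-like); log2-encoded files are decoded to the linear scale on
#' read, since all downstream ratio features are defined on raw expression.
#'
#' @param path Path to a delimited text file.
#' @param scale_tag Either `"linear"` (values stored as raw expression) or
#'   `"log2"` (values stored as `log2(expression + pseudocount_floor)`; they
#'   are decoded as `2^x - pseudocount_floor`, clamped at 0).
#' @param pseudocount_floor Pseudocount used by the on-disk log2 encoding.
#'   Default 0; set to 0.1 to invert a `log2(FPKM + 0.1)` encoding exactly.
#' @param probe_map Optional probe-to-gene map (see [read_probe_map()]). When
#'   supplied, rows are treated as probes, duplicates are allowed, and the
#'   matrix is collapsed to gene level with [collapse_probes()].
#' @param collapse_mode Passed to [collapse_probes()] when `probe_map` is
#'   given.
#' @return A numeric genes-by-samples matrix on the linear scale, gene symbols
#'   as rownames, sample ids as colnames.
#' @export
read_expression <- function(path, scale_tag = c("linear", "log2"),
                            pseudocount_floor = 0, probe_map = NULL,
                            collapse_mode = c("per_sample_max", "global_max_probe")) {
  scale_tag <- match.arg(scale_tag)
  .assert_scalar_number(pseudocount_floor, "pseudocount_floor", lower = 0)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) {
    abort("Expression file needs an id column plus at least one sample column.")
  }
  ids <- as.character(df[[1L]])
  vals <- as.data.frame(df[-1L])
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num)) {
    abort(sprintf("Non-numeric expression column(s): %s.",
                  paste(non_num, collapse = ", ")))
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (any(!is.finite(mat))) {
    abort("Expression file contains missing or non-finite values.")
  }
  if (scale_tag == "log2") {
    mat <- pmax(2^mat - pseudocount_floor, 0)
  } else if (any(mat < 0)) {
    abort("Negative values found in a matrix declared linear-scale.")
  }
  if (!is.null(probe_map)) {
    return(collapse_probes(mat, probe_map, mode = match.arg(collapse_mode)))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf(
      "Duplicated gene id(s): %s. Supply `probe_map` to collapse probe-level data.",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  mat
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()] for linear-scale matrices; values are
#' written at full precision so a read/write/read round trip is lossless.
#'
#' @param mat Numeric genes-by-samples matrix.
#' @param path Output path (`.csv` selects comma-delimited output, otherwise
#'   tab-delimited).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  .check_expression(mat)
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Read or write a sample-to-subtype label table
#'
#' Two-column delimited text: `sample_id`, `subtype`. Subtypes must come from
#' [subtype_levels()] and each sample may carry at most one label.
#'
#' @param path Path to a two-column TSV.
#' @return A tibble with columns `sample_id` and `subtype`.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(df)[1:2] <- c("sample_id", "subtype")
  .check_labels(df)
}

#' @rdname read_labels
#' @param labels A label table.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(.check_labels(labels), path)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column delimited text: `probe_id`, `gene_symbol`. Many probes may map
#' to one gene; each probe must map to exactly one gene.
#'
#' @param path Path to a two-column TSV.
#' @return A tibble with columns `probe_id` and `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(df)[1:2] <- c("probe_id", "gene_symbol")
  if (anyDuplicated(df$probe_id)) {
    abort("Probe map assigns some probe to more than one gene.")
  }
  tibble::as_tibble(df[c("probe_id", "gene_symbol")])
}

#' Collapse probe-level rows to gene level
#'
#' Selects a representative expression value per gene from its probes. The
#' default takes, for each gene and each sample independently, the maximum
#' value over that gene's probes in that sample. This per-sample rule depends
#' only on the sample's own measurements, so the collapsed value is unaffected
#' by the size or subtype composition of the rest of the cohort — the same
#' property the classifier itself is built around. The alternative
#' `"global_max_probe"` mode picks, per gene, the single probe with the
#' largest grand total across samples and uses that probe's row everywhere.
#'
#' @param mat Numeric probes-by-samples matrix (probe ids as rownames;
#'   duplicated rownames are not required — probes are matched through `map`).
#' @param map Probe-to-gene map, as from [read_probe_map()].
#' @param mode Collapse rule; see Details.
#' @return A genes-by-samples matrix with one row per mapped gene, rows
#'   sorted by gene symbol (so the result does not depend on probe row order).
#' @export
collapse_probes <- function(mat, map,
                            mode = c("per_sample_max", "global_max_probe")) {
  mode <- match.arg(mode)
  if (!is.matrix(mat) || !is.numeric(mat) || is.null(rownames(mat))) {
    abort("`mat` must be a numeric matrix with probe ids as rownames.")
  }
  if (!is.data.frame(map) || !all(c("probe_id", "gene_symbol") %in% names(map))) {
    abort("`map` must have columns `probe_id` and `gene_symbol`.")
  }
  gene_of <- setNames(as.character(map$gene_symbol), as.character(map$probe_id))
  probes <- rownames(mat)
  unmapped <- unique(probes[!(probes %in% names(gene_of))])
  if (length(unmapped)) {
    abort(sprintf("Probe(s) absent from map: %s.",
                  paste(head(unmapped, 10), collapse = ", ")))
  }
  genes <- gene_of[probes]
  # sorted gene order keeps the result invariant to probe row order
  gene_order <- sort(unique(unname(genes)))
  out <- matrix(NA_real_, nrow = length(gene_order), ncol = ncol(mat),
                dimnames = list(gene_order, colnames(mat)))
  for (g in gene_order) {
    rows <- which(genes == g)
    block <- mat[rows, , drop = FALSE]
    out[g, ] <- if (mode == "per_sample_max") {
      apply(block, 2L, max)
    } else {
      block[which.max(rowSums(block)), ]
    }
  }
  out
}
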