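#' Assemble a seed-plus-level candidate gene set
#'
#' Builds the level-k input gene set: the seed genes followed by the top-k
#' ranked subtype-specific genes of each subtype, deduplicated while
#' preserving insertion order. Genes are appended rank-major — all rank-1
#' genes across the subtypes (in [subtype_levels()] order), then all rank-2
#' genes, and so on — so the level-k set is always an ordered prefix-extension
#' of the level-(k-1) set built from the same table.
#'
#' @param seeds Character vector of seed genes placed first (may be empty).
#' @param table Ranked subtype-specific gene table with columns `gene`,
#'   `subtype`, `rank` (e.g. [call_ssdegs()] output or [ssdeg_reference()]).
#' @param k Level depth: how many ranks per subtype to include (`k >= 0`).
#' @return Character vector of unique gene symbols with attributes `level`
#'   (k) and `provenance` (a tibble recording where each gene came from).
#' @export
#' @examples
#' build_gene_set(seed_genes(), ssdeg_reference(), k = 2)
build_gene_set <- function(seeds, table, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k)) {
    abort("`k` must be a single non-negative integer.")
  }
  if (!is.data.frame(table) || !all(c("gene", "subtype", "rank") %in% names(table))) {
    abort("`table` must have columns `gene`, `subtype`, `rank`.")
  }
  seeds <- as.character(seeds)
  if (anyDuplicated(seeds)) {
    abort("`seeds` contains duplicates.")
  }
  subs <- intersect(subtype_levels(), unique(table$subtype))
  if (k > 0) {
    depth <- vapply(subs, function(st) {
      max(0L, table$rank[table$subtype == st])
    }, integer(1))
    short <- subs[depth < k]
    if (length(short)) {
      abort(sprintf("Subtype(s) with fewer than %d ranked genes: %s.",
                    k, paste(short, collapse = ", ")))
    }
  }
  prov <- tibble(gene = seeds,
                 provenance = rep("seed", length(seeds)))
  if (k > 0) {
    for (r in seq_len(k)) {
      for (st in subs) {
        g <- table$gene[table$subtype == st & table$rank == r]
        prov <- dplyr::bind_rows(prov, tibble(
          gene = g, provenance = sprintf("ssDEG(%s, rank %d)", st, r)
        ))
      }
    }
  }
  prov <- dplyr::distinct(prov, .data$gene, .keep_all = TRUE)
  genes <- prov$gene
  if (!length(genes)) {
    abort("Empty gene set: supply seeds and/or k > 0.")
  }
  structure(genes, level = as.integer(k), provenance = prov)
}

#' Pairwise gene expression ratio (PGER)
#'
#' The core single-sample feature: `r = log2((e_i + 1) / (e_j + 1))` for two
#' raw linear-scale expression values of the same sample. The +1 pseudocount
#' keeps the ratio defined at zero expression; because both values come from
#' one sample, the feature needs no cohort normalisation.
#'
#' @param e_i,e_j Non-negative linear-scale expression values (vectorised).
#' @return `log2((e_i + 1) / (e_j + 1))`.
#' @export
pger <- function(e_i, e_j) {
  if (any(e_i < 0) || any(e_j < 0)) {
    abort("Expression values must be non-negative (linear scale).")
  }
  log2((e_i + 1) / (e_j + 1))
}

#' Slack margin soft-threshold
#'
#' Treats expression ratios within `alpha` of zero as experimental noise:
#' `0` when `|r| <= alpha`, `r - alpha` when `r > alpha`, `r + alpha` when
#' `r < -alpha`. Equivalently `sign(r) * max(0, |r| - alpha)`.
#'
#' @param r Ratio value(s).
#' @param alpha Slack margin, `alpha >= 0`.
#' @return Soft-thresholded ratio(s).
#' @export
slack_transform <- function(r, alpha) {
  .assert_scalar_number(alpha, "alpha", lower = 0)
  sign(r) * pmax(0, abs(r) - alpha)
}

#' Build the sample-by-pair PGER feature matrix
#'
#' Computes the slack-thresholded pairwise log2 expression ratio for every
#' unordered gene pair of a gene set, for every sample. Columns are named
#' `"Gi/Gj"` with i < j in gene-set order and are ordered lexicographically in
#' the index pair (i, j); this fixed orientation is part of the stable model
#' contract (the mirrored ratio is just the negation and is never emitted).
#' An n-gene set yields n(n-1)/2 columns.
#'
#' @param mat Linear-scale genes-by-samples matrix containing all `genes`.
#' @param genes Ordered gene set (e.g. from [build_gene_set()]).
#' @param alpha Slack margin applied to every ratio.
#' @return A samples-by-pairs numeric matrix of class `"pger_features"` with
#'   attributes `alpha` and `genes`.
#' @export
feature_matrix <- function(mat, genes, alpha = 0) {
  .check_expression(mat)
  .assert_scalar_number(alpha, "alpha", lower = 0)
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing)) {
    abort(sprintf("Gene(s) absent from the matrix: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(genes)) {
    abort("`genes` contains duplicates.")
  }
  le <- t(log2(mat[genes, , drop = FALSE] + 1)) # samples x genes
  idx <- utils::combn(length(genes), 2L)
  r <- le[, idx[1L, ], drop = FALSE] - le[, idx[2L, ], drop = FALSE]
  r <- sign(r) * pmax(0, abs(r) - alpha)
  dimnames(r) <- list(colnames(mat), .pair_names(genes))
  structure(r, alpha = alpha, genes = genes, class = c("pger_features", class(r)))
}

#' @method as_tibble pger_features
#' @export
as_tibble.pger_features <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "sample_id")
}

#' Write a PGER feature matrix to TSV
#'
#' @param features A `"pger_features"` matrix from [feature_matrix()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(as_tibble.pger_features(features), path)
  invisible(path)
}

#' Per-feature subtype separation (Kruskal-Wallis)
#'
#' Tests, for each PGER column, whether the feature differs among the
#' subtypes (Kruskal-Wallis rank test). A feature constant across all samples
#' has no rank signal; it is reported with `p_value = 1` and flagged
#' `degenerate`.
#'
#' @param features A `"pger_features"` matrix (or any samples-by-features
#'   numeric matrix with sample rownames).
#' @param labels Label table covering the feature rows; at least two subtypes
#'   must be present.
#' @return Tibble with columns `feature`, `p_value`, `degenerate`.
#' @export
feature_subtype_separation <- function(features, labels) {
  y <- .label_factor(labels, rownames(features))
  y <- droplevels(y)
  if (nlevels(y) < 2L) {
    abort("Need at least two subtypes for the Kruskal-Wallis test.")
  }
  ps <- apply(unclass(features), 2L, function(v) {
    if (length(unique(v)) == 1L) return(NA_real_)
    stats::kruskal.test(v, y)$p.value
  })
  ps <- unname(ps)
  tibble(
    feature = colnames(features),
    p_value = ifelse(is.na(ps), 1, ps),
    degenerate = is.na(ps)
  )
}
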