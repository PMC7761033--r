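#' One-vs-rest Wilcoxon rank-sum test for a single gene
#'
#' Tests whether a gene's expression in one subtype differs from its
#' expression in all remaining samples. The two-sided p-value is exact when
#' the combined group size is at most 25 and the values carry no ties;
#' otherwise the normal approximation with tie and continuity correction is
#' used. Direction is `"up"` when the gene's median in the subtype exceeds its
#' median in the remaining samples, `"down"` otherwise (exactly equal medians
#' are reported as `"down"` — an arbitrary but deterministic tie-break).
#'
#' @param mat Linear-scale genes-by-samples expression matrix.
#' @param labels Label table (`sample_id`, `subtype`) covering all columns of
#'   `mat`.
#' @param subtype The subtype forming the "one" group.
#' @param gene Gene symbol to test.
#' @return One-row tibble: `gene`, `subtype`, `p_value`, `direction`.
#' @export
wilcoxon_one_vs_rest <- function(mat, labels, subtype, gene) {
  .check_expression(mat)
  y <- .label_factor(labels, colnames(mat))
  if (!subtype %in% subtype_levels()) {
    abort(sprintf("Unknown subtype `%s`.", subtype))
  }
  if (!subtype %in% y) {
    abort(sprintf("Subtype `%s` has no samples in `labels`.", subtype))
  }
  if (!gene %in% rownames(mat)) {
    abort(sprintf("Gene `%s` absent from the expression matrix.", gene))
  }
  grp <- y == subtype
  if (sum(grp) < 2L || sum(!grp) < 2L) {
    abort(sprintf("Need >= 2 samples in `%s` and in the rest.", subtype))
  }
  res <- .rank_sum(mat[gene, ], grp)
  tibble(gene = gene, subtype = subtype,
         p_value = res$p_value, direction = res$direction)
}

# Core two-sided rank-sum test on a numeric vector split by a logical group.
.rank_sum <- function(x, grp) {
  a <- x[grp]
  b <- x[!grp]
  dir <- if (median(a) > median(b)) "up" else "down"
  if (length(unique(x)) == 1L) {
    # no rank signal at all; degenerate zero-variance case
    return(list(p_value = 1, direction = dir))
  }
  exact <- length(x) <= 25L && !anyDuplicated(x)
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  list(p_value = min(p, 1), direction = dir)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment of a vector of p-values: monotone non-decreasing in
#' p-rank and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must be finite numbers in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Call subtype-specific differentially expressed genes
#'
#' Screens a gene universe for subtype-specific expression by one-vs-rest
#' Wilcoxon rank-sum tests. For each subtype every gene in the universe is
#' tested against the remaining samples and BH correction is applied within
#' that subtype's family of tests; these are the reported `p_value`,
#' `q_value` and `direction`.
#'
#' Specificity is then decided in a second stage. A gene significant
#' (`q < q_threshold`) in at least one subtype is provisionally assigned to
#' its smallest-q subtype; the assignment stands only if, after removing
#' that subtype's samples from the cohort, no other subtype's one-vs-rest
#' test on the remaining samples stays significant (BH within each residual
#' family). This residual check is what "significant in only one subtype"
#' has to mean operationally: a gene cleanly shifted in a single subtype
#' contaminates the "rest" group of every other subtype's test and would
#' otherwise be flagged there too at large sample sizes, while a gene truly
#' shifted in two subtypes keeps its second signal after the first subtype
#' is removed and is excluded. A gene significant nowhere is still retained,
#' assigned to the subtype where its q is smallest and flagged
#' `passed_threshold = FALSE`, so that weak classes (typically the small,
#' contested Normal-like class) can still contribute ranked genes to
#' gene-set assembly. Within each subtype genes are ranked by ascending q,
#' ties broken by ascending raw p then gene symbol.
#'
#' @param mat Linear-scale genes-by-samples matrix.
#' @param labels Label table covering all samples; every present subtype needs
#'   at least 2 samples.
#' @param gene_universe Genes to screen (default: the PAM50 list). Every
#'   universe gene must be present in the matrix; missing genes raise an
#'   error rather than being dropped silently.
#' @param q_threshold FDR significance threshold (default 0.005).
#' @return A tibble with columns `gene`, `subtype`, `p_value`, `q_value`,
#'   `direction`, `rank`, `passed_threshold`; one row per retained gene.
#' @export
call_ssdegs <- function(mat, labels, gene_universe = pam50_genes(),
                        q_threshold = 0.005) {
  .check_expression(mat)
  y <- .label_factor(labels, colnames(mat))
  .assert_scalar_number(q_threshold, "q_threshold", lower = 0)
  missing <- setdiff(gene_universe, rownames(mat))
  if (length(missing)) {
    abort(sprintf("Gene(s) absent from the matrix: %s.",
                  paste(head(missing, 10), collapse = ", ")))
  }
  present <- levels(droplevels(y))
  if (length(present) < 2L) {
    abort("Need at least two subtypes to run one-vs-rest tests.")
  }
  sizes <- table(y)[present]
  if (any(sizes < 2L)) {
    abort(sprintf("Subtype(s) with < 2 samples: %s.",
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }

  tested <- purrr::map_dfr(present, function(st) {
    grp <- y == st
    res <- purrr::map(gene_universe, function(g) .rank_sum(mat[g, ], grp))
    tibble(
      gene = gene_universe,
      subtype = st,
      p_value = purrr::map_dbl(res, "p_value"),
      direction = purrr::map_chr(res, "direction")
    )
  })
  tested <- dplyr::mutate(dplyr::group_by(tested, .data$subtype),
                          q_value = bh_adjust(.data$p_value))
  tested <- dplyr::ungroup(tested)

  # provisional assignment: smallest q (ties: raw p, canonical subtype order)
  pick_best <- function(d) {
    d[order(d$q_value, d$p_value, match(d$subtype, subtype_levels()))[1L], ]
  }
  best <- dplyr::group_modify(dplyr::group_by(tested, .data$gene),
                              function(d, key) pick_best(d))
  best <- dplyr::ungroup(best)
  best$significant <- best$q_value < q_threshold

  # residual check for significant genes: with the assigned subtype's samples
  # removed, no other subtype may stay significant (BH within each residual
  # (assigned, other) family across the genes that need the check)
  excluded <- character(0)
  sig <- best[best$significant, ]
  for (t_st in unique(sig$subtype)) {
    genes_t <- sig$gene[sig$subtype == t_st]
    keep <- y != t_st
    y_res <- droplevels(y[keep])
    others <- levels(y_res)[table(y_res) >= 2L]
    for (u_st in others) {
      grp_u <- y_res == u_st
      p_res <- vapply(genes_t, function(g) {
        .rank_sum(mat[g, keep], grp_u)$p_value
      }, numeric(1))
      excluded <- union(excluded,
                        genes_t[bh_adjust(p_res) < q_threshold])
    }
  }
  assigned <- best[!(best$gene %in% excluded), ]

  out <- dplyr::arrange(assigned, match(.data$subtype, subtype_levels()),
                        .data$q_value, .data$p_value, .data$gene)
  out <- dplyr::mutate(dplyr::group_by(out, .data$subtype),
                       rank = dplyr::row_number())
  out <- dplyr::ungroup(out)
  dplyr::select(
    dplyr::mutate(out, passed_threshold = .data$q_value < q_threshold),
    "gene", "subtype", "p_value", "q_value", "direction", "rank",
    "passed_threshold"
  )
}

#' Write a subtype-specific DEG table to TSV
#'
#' @param table A tibble as returned by [call_ssdegs()].
#' @param path Output path.
#' @export
write_ssdegs <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
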