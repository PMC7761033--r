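#' Intrinsic breast cancer subtype names
#'
#' The five PAM50-style intrinsic subtypes in the fixed canonical order used
#' throughout the package (gene-set assembly, vote tallies, confusion
#' matrices).
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' subtype_levels()
subtype_levels <- function() {
  c("Basal-like", "Her2E", "LumA", "LumB", "Normal-like")
}

#' Clinical seed marker genes
#'
#' The four clinically established breast cancer markers (estrogen receptor,
#' progesterone receptor, HER2 and the Ki-67 proliferation marker) that are
#' pre-included in every candidate gene set before ranked subtype-specific
#' genes are added.
#'
#' @return Character vector of length 4.
#' @export
seed_genes <- function() {
  c("ESR1", "PGR", "ERBB2", "MKI67")
}

#' The PAM50 gene list
#'
#' The 50 genes of the PAM50 intrinsic subtype signature, used as the default
#' gene universe for subtype-specific differential expression screening.
#' Restricting the screen to these well-characterised subtype genes keeps the
#' candidate pool functionally interpretable and shrinks the combinatorial
#' search space of gene subsets by many orders of magnitude.
#'
#' @return Character vector of 50 gene symbols (current HGNC symbols; NUF2,
#'   NDC80 and ORC6 replace the legacy aliases CDCA1, KNTC2 and ORC6L).
#' @export
pam50_genes <- function() {
  c(
    "ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1",
    "CDC20", "CDC6", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR", "ERBB2",
    "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7", "KIF2C",
    "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67",
    "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "NDC80", "NUF2", "ORC6",
    "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B",
    "TYMS", "UBE2C", "UBE2T"
  )
}

#' The slack margin grid
#'
#' Default grid of slack margin values \eqn{\alpha} over which the ensemble is
#' trained. A pairwise log2 expression ratio whose absolute value falls below
#' \eqn{\alpha} is treated as experimental noise and zeroed; larger ratios are
#' shrunk toward zero by \eqn{\alpha}.
#'
#' @return Numeric vector of 7 values.
#' @export
alpha_grid <- function() {
  c(0.00, 0.01, 0.05, 0.10, 0.15, 0.20, 1.00)
}

#' The shipped 11-gene classifier panel
#'
#' The reduced gene panel of the reference absolute single-sample classifier:
#' the four clinical seed markers plus seven subtype-specific genes retained
#' after Gini-importance-guided stepwise reduction of the 13-gene second-level
#' candidate set (GRB7 and KRT14 removed). FGFR4 is the growth-factor
#' signalling member of the panel; see the methods vignette for a note on its
#' naming.
#'
#' @return Character vector of 11 gene symbols.
#' @export
miniabs_panel <- function() {
  c(
    "ESR1", "PGR", "ERBB2", "MKI67",
    "MLPH", "FGFR4", "CEP55", "KRT17",
    "FOXA1", "MYBL2", "SFRP1"
  )
}

#' Reference table of top subtype-specific genes
#'
#' The published top-5 ranked subtype-specific differentially expressed genes
#' per intrinsic subtype, with their one-vs-rest Wilcoxon rank-sum p-values
#' and Benjamini-Hochberg false discovery rates from the 432-sample discovery
#' cohort. This table is an input to gene-set assembly: levels 1 and 2
#' combined with the seed genes reproduce the 8- and 13-gene candidate sets.
#'
#' A gene may appear under two subtypes here (e.g. ERBB2 under Her2E and
#' Normal-like): the Normal-like column ranks genes whose FDR (~0.24) never
#' reaches the 0.005 significance threshold, reflecting the weakness of that
#' contested, 7-sample class; `passed_threshold` records this. Gene-set
#' assembly deduplicates at union time.
#'
#' @param q_threshold FDR threshold used to populate `passed_threshold`.
#' @return A tibble with columns `gene`, `subtype`, `rank`, `p_value`,
#'   `q_value`, `passed_threshold`.
#' @export
ssdeg_reference <- function(q_threshold = 0.005) {
  tab <- tibble::tribble(
    ~subtype,      ~rank, ~gene,    ~p_value, ~q_value,
    "Basal-like",  1L,    "MLPH",   4.0e-41,  8.2e-37,
    "Basal-like",  2L,    "FOXA1",  9.6e-40,  6.6e-36,
    "Basal-like",  3L,    "FOXC1",  1.0e-38,  3.4e-35,
    "Basal-like",  4L,    "ESR1",   1.0e-35,  6.5e-33,
    "Basal-like",  5L,    "NAT1",   1.4e-35,  8.1e-33,
    "Her2E",       1L,    "FGFR4",  4.6e-19,  4.3e-15,
    "Her2E",       2L,    "GRB7",   5.6e-16,  7.7e-13,
    "Her2E",       3L,    "ERBB2",  1.4e-15,  1.6e-12,
    "Her2E",       4L,    "BCL2",   5.2e-14,  2.8e-11,
    "Her2E",       5L,    "ESR1",   3.6e-12,  9.5e-10,
    "LumA",        1L,    "CEP55",  2.4e-50,  1.2e-46,
    "LumA",        2L,    "MYBL2",  7.0e-49,  2.4e-45,
    "LumA",        3L,    "MELK",   3.8e-47,  5.2e-44,
    "LumA",        4L,    "KIF2C",  7.5e-47,  9.6e-44,
    "LumA",        5L,    "ANLN",   1.2e-46,  1.5e-43,
    "LumB",        1L,    "KRT17",  2.0e-20,  6.8e-17,
    "LumB",        2L,    "SFRP1",  7.7e-20,  1.6e-16,
    "LumB",        3L,    "KRT14",  5.7e-18,  4.3e-15,
    "LumB",        4L,    "KRT5",   1.6e-17,  8.7e-15,
    "LumB",        5L,    "EGFR",   1.1e-16,  5.0e-14,
    "Normal-like", 1L,    "ERBB2",  5.4e-3,   2.4e-1,
    "Normal-like", 2L,    "KRT14",  2.3e-3,   2.4e-1,
    "Normal-like", 3L,    "KRT5",   3.0e-3,   2.4e-1,
    "Normal-like", 4L,    "MIA",    3.2e-3,   2.4e-1,
    "Normal-like", 5L,    "SFRP1",  4.9e-3,   2.5e-1
  )
  dplyr::mutate(
    dplyr::select(tab, "gene", "subtype", "rank", "p_value", "q_value"),
    passed_threshold = .data$q_value < q_threshold
  )
}
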