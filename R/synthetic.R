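#' Default marker map for the synthetic cohort generator
#'
#' Assigns one subtype-specific expression shift to each of eight genes —
#' the four clinical seed markers plus four top subtype-specific genes —
#' with directions mirroring their biology (e.g. ERBB2 up in Her2E, MLPH
#' down in Basal-like). Each gene shifts in exactly one subtype, so at
#' sufficient effect size the one-vs-rest screen should recover every marker
#' for its subtype. The Normal-like marker is optional and, by default,
#' carries half the effect size: Normal-like is a small, weakly separated
#' class and the simulator reproduces that instability.
#'
#' @param delta Effect size in log2 units (default 2).
#' @param include_normal_like Add a (weaker) Normal-like marker, SFRP1.
#' @param normal_like_delta Effect size of the Normal-like marker.
#' @return Tibble with columns `gene`, `subtype`, `direction` (`"up"` /
#'   `"down"`), `delta`.
#' @export
default_markers <- function(delta = 2, include_normal_like = FALSE,
                            normal_like_delta = delta / 2) {
  m <- tibble::tribble(
    ~gene,    ~subtype,     ~direction,
    "MKI67",  "Basal-like", "up",
    "MLPH",   "Basal-like", "down",
    "ERBB2",  "Her2E",      "up",
    "FGFR4",  "Her2E",      "up",
    "ESR1",   "LumA",       "up",
    "CEP55",  "LumA",       "down",
    "PGR",    "LumB",       "up",
    "KRT17",  "LumB",       "up"
  )
  m$delta <- delta
  if (include_normal_like) {
    m <- dplyr::bind_rows(m, tibble(gene = "SFRP1", subtype = "Normal-like",
                                    direction = "up",
                                    delta = normal_like_delta))
  }
  m
}

#' Configuration for the synthetic subtype cohort generator
#'
#' @param n_per_class Named integer vector of samples per subtype. The
#'   default mirrors a realistic discovery cohort: 76 Basal-like, 50 Her2E,
#'   194 LumA, 105 LumB and 7 Normal-like (432 samples, with Normal-like as
#'   the characteristic rare class).
#' @param markers Marker map (`gene`, `subtype`, `direction`, `delta`); see
#'   [default_markers()].
#' @param n_noise_genes Number of additional pure-noise genes (`NOISE1`,
#'   `NOISE2`, ...), disjoint from the marker genes.
#' @param baseline_range Range of per-gene baseline log2 expression; each
#'   gene's baseline is drawn uniformly from it (RPKM-like magnitudes).
#' @param sigma Standard deviation of the log2-scale noise (log-normal noise
#'   on the linear scale).
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_per_class = c("Basal-like" = 76, "Her2E" = 50,
                                       "LumA" = 194, "LumB" = 105,
                                       "Normal-like" = 7),
                       markers = default_markers(), n_noise_genes = 10,
                       baseline_range = c(4, 9), sigma = 0.7, seed = 1) {
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% subtype_levels())) {
    abort("`n_per_class` must be named with subtype levels.")
  }
  if (any(n_per_class < 0)) abort("Class sizes must be >= 0.")
  if (!is.data.frame(markers) ||
      !all(c("gene", "subtype", "direction", "delta") %in% names(markers))) {
    abort("`markers` must have columns gene, subtype, direction, delta.")
  }
  if (any(markers$delta < 0)) abort("Marker effect sizes must be >= 0.")
  if (!all(markers$direction %in% c("up", "down"))) {
    abort("Marker directions must be \"up\" or \"down\".")
  }
  if (!all(markers$subtype %in% subtype_levels())) {
    abort("Marker subtypes must come from subtype_levels().")
  }
  if (anyDuplicated(markers$gene)) {
    abort("Each marker gene may shift in only one subtype.")
  }
  .assert_scalar_number(sigma, "sigma", lower = 0)
  if (sigma <= 0) abort("`sigma` must be > 0.")
  .assert_scalar_number(n_noise_genes, "n_noise_genes", lower = 0)
  structure(
    list(n_per_class = n_per_class, markers = tibble::as_tibble(markers),
         n_noise_genes = as.integer(n_noise_genes),
         baseline_range = baseline_range, sigma = sigma,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a subtype-structured expression cohort
#'
#' Generates a genes-by-samples matrix with known ground truth. On the log2
#' scale, the value of gene g in a sample of subtype t is
#' `baseline_g + delta_g * dir_g * [t == subtype(g)] + Normal(0, sigma)`;
#' the emitted linear value is `max(0, 2^x - 1)`, so that the +1-pseudocount
#' log ratio features recover log2-scale differences approximately. Noise
#' genes carry no subtype shift. The generator is deterministic given the
#' config seed.
#'
#' @param cfg A [sim_config()] object.
#' @return List with `expression` (linear-scale genes-by-samples matrix) and
#'   `labels` (tibble `sample_id`, `subtype`).
#' @export
simulate_subtypes <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a sim_config().")
  noise_genes <- if (cfg$n_noise_genes > 0) {
    paste0("NOISE", seq_len(cfg$n_noise_genes))
  } else {
    character(0)
  }
  clash <- intersect(noise_genes, cfg$markers$gene)
  if (length(clash)) {
    abort(sprintf("Marker genes clash with noise gene names: %s.",
                  paste(clash, collapse = ", ")))
  }
  genes <- c(cfg$markers$gene, noise_genes)
  classes <- names(cfg$n_per_class)[cfg$n_per_class > 0]
  subtype <- rep(classes, cfg$n_per_class[classes])
  sample_id <- sprintf("S%03d", seq_along(subtype))

  shift <- matrix(0, nrow = length(genes), ncol = length(subtype),
                  dimnames = list(genes, sample_id))
  for (i in seq_len(nrow(cfg$markers))) {
    mk <- cfg$markers[i, ]
    sgn <- if (mk$direction == "up") 1 else -1
    shift[mk$gene, subtype == mk$subtype] <- sgn * mk$delta
  }
  mat <- withr::with_seed(cfg$seed, {
    baseline <- runif(length(genes), cfg$baseline_range[1], cfg$baseline_range[2])
    x <- baseline + shift +
      matrix(rnorm(length(genes) * length(subtype), sd = cfg$sigma),
             nrow = length(genes))
    pmax(2^x - 1, 0)
  })
  dimnames(mat) <- list(genes, sample_id)
  list(expression = mat,
       labels = tibble(sample_id = sample_id, subtype = subtype))
}

#' Write the canonical synthetic fixture suite
#'
#' Emits four small matched expression/label fixture sets used by tests and
#' documentation, all derived deterministically from `seed`:
#' `separable` (strong five-class structure, delta 3, sigma 0.5),
#' `null` (no subtype signal at all),
#' `probes` (the separable set re-expressed at probe level, two probes per
#' marker gene, plus the probe map), and
#' `log2` (the separable set encoded as `log2(value + 0.1)`).
#' A `manifest.json` records the configuration and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_per_class Samples per class for the fixtures (small by design).
#' @param seed Integer seed.
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir,
                               n_per_class = c("Basal-like" = 6, "Her2E" = 6,
                                               "LumA" = 6, "LumB" = 6,
                                               "Normal-like" = 6),
                               seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, paste0(...))
  files <- c()

  sep_cfg <- sim_config(
    n_per_class = n_per_class,
    markers = default_markers(delta = 3, include_normal_like = TRUE,
                              normal_like_delta = 3),
    n_noise_genes = 5, sigma = 0.5, seed = seed
  )
  sep <- simulate_subtypes(sep_cfg)
  files["separable_expr"] <- write_expression(sep$expression, path("separable_expr.tsv"))
  files["separable_labels"] <- write_labels(sep$labels, path("separable_labels.tsv"))

  null_cfg <- sim_config(
    n_per_class = n_per_class,
    markers = default_markers(delta = 0, include_normal_like = TRUE,
                              normal_like_delta = 0),
    n_noise_genes = 5, sigma = 0.5, seed = seed + 1L
  )
  nul <- simulate_subtypes(null_cfg)
  files["null_expr"] <- write_expression(nul$expression, path("null_expr.tsv"))
  files["null_labels"] <- write_labels(nul$labels, path("null_labels.tsv"))

  # probe-level view: two probes per marker gene (the second attenuated so
  # the per-sample maximum recovers the gene row), one probe per noise gene
  marker_genes <- sep_cfg$markers$gene
  probe_rows <- list()
  probe_map <- list()
  for (g in rownames(sep$expression)) {
    if (g %in% marker_genes) {
      probe_rows[[paste0(g, "_p1")]] <- sep$expression[g, ]
      probe_rows[[paste0(g, "_p2")]] <- sep$expression[g, ] * 0.6
      probe_map[[g]] <- c(paste0(g, "_p1"), paste0(g, "_p2"))
    } else {
      probe_rows[[paste0(g, "_p1")]] <- sep$expression[g, ]
      probe_map[[g]] <- paste0(g, "_p1")
    }
  }
  probe_mat <- do.call(rbind, probe_rows)
  colnames(probe_mat) <- colnames(sep$expression)
  files["probes_expr"] <- write_expression(probe_mat, path("probes_expr.tsv"))
  map_tbl <- tibble(
    probe_id = unlist(probe_map, use.names = FALSE),
    gene_symbol = rep(names(probe_map), lengths(probe_map))
  )
  readr::write_tsv(map_tbl, path("probes_map.tsv"))
  files["probes_map"] <- path("probes_map.tsv")

  log2_df <- tibble::as_tibble(log2(sep$expression + 0.1), rownames = "gene_id")
  readr::write_tsv(log2_df, path("log2_expr.tsv"))
  files["log2_expr"] <- path("log2_expr.tsv")

  manifest <- list(
    format_version = "1.0", seed = seed, n_per_class = as.list(n_per_class),
    fixtures = list(
      separable = list(delta = 3, sigma = 0.5, n_noise_genes = 5),
      null = list(delta = 0, sigma = 0.5, n_noise_genes = 5),
      probes = list(derived_from = "separable", attenuation = 0.6),
      log2 = list(derived_from = "separable", pseudocount_floor = 0.1)
    ),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  files["manifest"] <- path("manifest.json")
  invisible(files)
}
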