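test_that("rank-sum p matches exact enumeration for complete separation", {
  d <- two_group_mat(c(10, 11, 12), c(1, 2, 3))
  res <- wilcoxon_one_vs_rest(d$mat, d$labels, "LumA", "G1")
  expect_equal(res$p_value, enumerate_ranksum_p(c(10, 11, 12), c(1, 2, 3)))
  expect_equal(res$p_value, 2 / choose(6, 3)) # 2/20 at n=(3,3)
  expect_equal(res$direction, "up")
})

test_that("identical constant groups give p = 1, direction down", {
  d <- two_group_mat(rep(5, 4), rep(5, 4))
  res <- wilcoxon_one_vs_rest(d$mat, d$labels, "LumA", "G1")
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "down")
})

test_that("swapping the one-vs-rest roles flips direction, keeps p", {
  d <- two_group_mat(c(8, 9, 13, 20), c(1, 2, 3, 7))
  up <- wilcoxon_one_vs_rest(d$mat, d$labels, "LumA", "G1")
  down <- wilcoxon_one_vs_rest(d$mat, d$labels, "LumB", "G1")
  expect_equal(up$p_value, down$p_value)
  expect_equal(up$direction, "up")
  expect_equal(down$direction, "down")
})

test_that("rank-sum guards unknown subtype / missing gene / tiny groups", {
  d <- two_group_mat(c(1, 2, 3), c(4, 5, 6))
  expect_error(wilcoxon_one_vs_rest(d$mat, d$labels, "Basal-like", "G1"),
               "no samples")
  expect_error(wilcoxon_one_vs_rest(d$mat, d$labels, "LumA", "NOPE"),
               "absent")
  d1 <- two_group_mat(7, c(1, 2, 3))
  expect_error(wilcoxon_one_vs_rest(d1$mat, d1$labels, "LumA", "G1"),
               ">= 2 samples")
})

test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("a gene shifted in one subtype is that subtype's top-ranked call", {
  sim <- quick_sim(n = 30, delta = 3, sigma = 0.5, seed = 101)
  tab <- call_ssdegs(sim$expression, sim$labels,
                     gene_universe = rownames(sim$expression))
  markers <- default_markers(delta = 3, include_normal_like = TRUE,
                             normal_like_delta = 3)
  # each subtype's rank-1 gene is one of its planted markers, right direction
  for (st in subtype_levels()) {
    top <- tab[tab$subtype == st & tab$rank == 1, ]
    planted <- markers[markers$subtype == st, ]
    expect_true(top$gene %in% planted$gene)
    expect_equal(top$direction,
                 planted$direction[planted$gene == top$gene])
    expect_true(top$passed_threshold)
  }
})

test_that("a gene shifted equally in two subtypes is excluded", {
  markers <- tibble::tibble(
    gene = c("SHARED_A", "SHARED_B", "ONLY1"),
    subtype = c("LumA", "LumB", "Her2E"),
    direction = "up", delta = 3
  )
  cfg <- sim_config(n_per_class = setNames(rep(25, 5), subtype_levels()),
                    markers = markers, n_noise_genes = 3, sigma = 0.5,
                    seed = 9)
  sim <- simulate_subtypes(cfg)
  # plant the same shift in a second subtype by overwriting SHARED_B with
  # SHARED_A's generating pattern: simulate a single gene up in both Luminals
  lab <- sim$labels
  both <- lab$subtype %in% c("LumA", "LumB")
  sim$expression["SHARED_A", both] <- sim$expression["SHARED_A", both] * 8
  tab <- call_ssdegs(sim$expression, lab,
                     gene_universe = rownames(sim$expression))
  expect_false("SHARED_A" %in% tab$gene) # significant in both -> dropped
  expect_true("ONLY1" %in% tab$gene[tab$subtype == "Her2E"])
})

test_that("pure-noise matrices yield no significant calls", {
  sim <- quick_sim(n = 20, delta = 0, sigma = 0.5, n_noise = 5, seed = 77,
                   normal_like_delta = 0)
  tab <- call_ssdegs(sim$expression, sim$labels,
                     gene_universe = rownames(sim$expression))
  expect_equal(sum(tab$passed_threshold), 0L)
  # but genes are still ranked (with the sub-threshold flag), 1..K per subtype
  ranks <- split(tab$rank, tab$subtype)
  for (r in ranks) expect_equal(sort(r), seq_along(r))
})

test_that("ssDEG output is invariant to sample order and reproducible", {
  sim <- quick_sim(n = 15, seed = 5)
  tab <- call_ssdegs(sim$expression, sim$labels,
                     gene_universe = rownames(sim$expression))
  perm <- sample(ncol(sim$expression))
  tab2 <- call_ssdegs(sim$expression[, perm],
                      sim$labels[match(colnames(sim$expression)[perm],
                                       sim$labels$sample_id), ],
                      gene_universe = rownames(sim$expression))
  expect_equal(tab, tab2)
  # every reported p is reproduced by re-running the single-gene test
  for (i in sample(nrow(tab), 5)) {
    row <- tab[i, ]
    re <- wilcoxon_one_vs_rest(sim$expression, sim$labels, row$subtype,
                               row$gene)
    expect_identical(re$p_value, row$p_value)
    expect_identical(re$direction, row$direction)
  }
})

test_that("each gene is assigned to at most one subtype", {
  sim <- quick_sim(n = 15, seed = 31)
  tab <- call_ssdegs(sim$expression, sim$labels,
                     gene_universe = rownames(sim$expression))
  expect_equal(anyDuplicated(tab$gene), 0L)
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
})

test_that("call_ssdegs rejects subtypes with fewer than two samples", {
  sim <- quick_sim(n = 10, seed = 3, n_normal = 1)
  expect_error(
    call_ssdegs(sim$expression, sim$labels,
                gene_universe = rownames(sim$expression)),
    "Normal-like"
  )
})
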