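# A fitted RF on a separable cohort, shared across importance tests.
sim33 <- quick_sim(n = 12, delta = 3, sigma = 0.5, seed = 33)
feats33 <- feature_matrix(sim33$expression, rownames(sim33$expression)[1:6],
                          alpha = 0)
rf_model <- fast_cv_train(feats33, sim33$labels, "rf", seed = 34)
nb_model <- fast_cv_train(feats33, sim33$labels, "nb", seed = 34)

test_that("gene importance is the sum over incident pair features", {
  imp <- gene_importance(rf_model)
  feats <- imp$features
  # recompute by hand from the per-feature scores
  for (g in imp$genes$gene) {
    incident <- vapply(strsplit(feats$feature, "/", fixed = TRUE),
                       function(p) g %in% p, logical(1))
    expect_equal(imp$genes$importance[imp$genes$gene == g],
                 sum(feats$importance[incident]))
  }
  # conservation: each feature contributes to exactly two genes
  expect_equal(sum(imp$genes$importance), 2 * sum(feats$importance))
  expect_setequal(imp$genes$rank, seq_len(nrow(imp$genes)))
  expect_error(gene_importance(nb_model), "random forest")
})

test_that("hand-built feature importances aggregate as defined", {
  fake <- rf_model
  # A/B:2, A/C:4, B/C:6 -> A=6, B=8, C=10
  fake$feature_names <- c("A/B", "A/C", "B/C")
  fake$fit <- structure(list(), class = "fake_rf")
  local_mocked_bindings(
    importance = function(fit, ...) {
      matrix(c(2, 4, 6), ncol = 1, dimnames = list(NULL, "MeanDecreaseGini"))
    },
    .package = "randomForest"
  )
  imp <- gene_importance(fake)
  expect_equal(imp$genes$gene, c("C", "B", "A")) # descending importance
  expect_equal(imp$genes$importance, c(10, 8, 6))

  # single pair: both genes tied, broken lexicographically
  fake$feature_names <- "A/B"
  local_mocked_bindings(
    importance = function(fit, ...) {
      matrix(5, ncol = 1, dimnames = list(NULL, "MeanDecreaseGini"))
    },
    .package = "randomForest"
  )
  imp2 <- gene_importance(fake)
  expect_equal(imp2$genes$gene, c("A", "B"))
  expect_equal(imp2$genes$importance, c(5, 5))
  expect_equal(imp2$genes$rank, 1:2)
})

test_that("the importance gap splits informative from uninformative genes", {
  scores <- c(60.95, 55, 50, 48, 45, 42, 40.19, 24.0, 23, 22, 21, 20.5, 20.25)
  expect_equal(detect_importance_gap(scores), 7L)
  expect_equal(detect_importance_gap(c(10, 8, 6, 4, 2)), 1L) # linear decline
  expect_equal(detect_importance_gap(c(9, 9, 9, 3, 3, 3)), 3L) # two plateaus
  expect_error(detect_importance_gap(c(2, 1)), "at least 3")
})

test_that("reduction stops after the accuracy drop and spends slack on panel size", {
  imp <- structure(list(genes = tibble::tibble(
    gene = paste0("G", 1:13),
    importance = seq(130, 10, by = -10),
    rank = 1:13
  )), class = "miniabs_importance")
  initial <- structure(list(
    algorithm = "rf", alpha = 0, genes = paste0("G", 1:13),
    cv_accuracy = 0.8804
  ), class = "miniabs_model")
  scripted <- c(0.8826, 0.8824, 0.8412, 0.9, 0.9, 0.9)
  hook <- function(genes, step) list(cv_accuracy = scripted[step])

  red <- reduce_genes(initial, importance = imp, protected_count = 7,
                      drop_tolerance = 0.005, retrain = hook)
  # removals proceed from the lowest-ranked gene upward and stop at the drop
  expect_equal(red$path$removed_gene, c(NA, "G13", "G12", "G11"))
  expect_equal(red$path$cv_accuracy, c(0.8804, 0.8826, 0.8824, 0.8412))
  # 11-gene model chosen: within tolerance of the best and smallest
  expect_equal(red$path$n_genes[red$path$selected], 11L)
  expect_equal(red$genes, paste0("G", 1:11))
})

test_that("monotone gains reduce to the protected floor; an immediate drop keeps the initial model", {
  imp <- structure(list(genes = tibble::tibble(
    gene = paste0("G", 1:10), importance = 10:1, rank = 1:10
  )), class = "miniabs_importance")
  initial <- structure(list(
    algorithm = "rf", alpha = 0, genes = paste0("G", 1:10),
    cv_accuracy = 0.80
  ), class = "miniabs_model")

  rising <- function(genes, step) list(cv_accuracy = 0.80 + 0.02 * step)
  red <- reduce_genes(initial, importance = imp, protected_count = 6,
                      retrain = rising)
  expect_equal(max(red$path$step), 4L) # ran to the protected floor
  expect_equal(red$path$n_genes[red$path$selected], 6L)

  dropping <- function(genes, step) list(cv_accuracy = 0.70)
  red2 <- reduce_genes(initial, importance = imp, protected_count = 6,
                       retrain = dropping)
  expect_equal(max(red2$path$step), 1L)
  expect_true(red2$path$selected[red2$path$step == 0])
  expect_equal(red2$genes, initial$genes)
})

test_that("end-to-end reduction on planted data removes only noise genes", {
  sim <- quick_sim(n = 25, delta = 2, sigma = 0.7, n_noise = 5, seed = 41,
                   include_normal_like = FALSE)
  genes13 <- rownames(sim$expression) # 8 informative + 5 noise
  expect_length(genes13, 13L)
  feats <- feature_matrix(sim$expression, genes13, alpha = 0)
  initial <- cv_train(feats, sim$labels, "rf", folds = 5, repeats = 1,
                      tune_grid_size = 1, seed = 42, ntree = 150)
  red <- reduce_genes(initial, sim$expression, sim$labels, seed = 43)
  removed <- red$path$removed_gene[red$path$step > 0]
  expect_true(all(grepl("^NOISE", removed)))
  expect_true(all(default_markers()$gene %in% red$genes))
})
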