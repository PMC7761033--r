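test_that("stratified split preserves class proportions and is seeded", {
  sim <- quick_sim(n = 20, seed = 2)
  sp <- split_train_test(sim$expression, sim$labels, ratio = 0.8, seed = 4)
  train_tab <- table(sp$train$labels$subtype)
  test_tab <- table(sp$test$labels$subtype)
  expect_true(all(train_tab == 16))
  expect_true(all(test_tab == 4))
  # disjoint and exhaustive
  expect_length(intersect(sp$train$labels$sample_id,
                          sp$test$labels$sample_id), 0L)
  expect_setequal(c(sp$train$labels$sample_id, sp$test$labels$sample_id),
                  colnames(sim$expression))
  # same seed -> identical partition; different seed -> different partition
  sp2 <- split_train_test(sim$expression, sim$labels, ratio = 0.8, seed = 4)
  expect_identical(sp$train$labels, sp2$train$labels)
  sp3 <- split_train_test(sim$expression, sim$labels, ratio = 0.8, seed = 5)
  expect_false(identical(sp$train$labels$sample_id,
                         sp3$train$labels$sample_id))
})

test_that("split guards degenerate ratios and tiny classes", {
  sim <- quick_sim(n = 10, seed = 2)
  expect_error(split_train_test(sim$expression, sim$labels, ratio = 1),
               "strictly between")
  expect_error(split_train_test(sim$expression, sim$labels, ratio = 0),
               "strictly between")
  sim1 <- quick_sim(n = 10, seed = 2, n_normal = 1)
  expect_error(split_train_test(sim1$expression, sim1$labels),
               "Normal-like")
})

test_that("cv_train separates a strong two-class problem and is deterministic", {
  sim <- quick_sim(n = 20, delta = 3, sigma = 0.5, seed = 6)
  keep <- sim$labels$subtype %in% c("Basal-like", "LumA")
  mat <- sim$expression[, keep]
  labels <- sim$labels[keep, ]
  feats <- feature_matrix(mat, rownames(mat)[1:8], alpha = 0)
  m <- fast_cv_train(feats, labels, "rf", seed = 11)
  expect_gte(m$cv_accuracy, 0.95)
  m2 <- fast_cv_train(feats, labels, "rf", seed = 11)
  expect_identical(m$cv_accuracy, m2$cv_accuracy)
  expect_identical(m$best_params, m2$best_params)
  expect_identical(predict(m, mat), predict(m2, mat))
})

test_that("cv accuracy under permuted labels sits near chance", {
  sim <- quick_sim(n = 16, delta = 3, sigma = 0.5, seed = 14)
  perm_labels <- sim$labels
  perm_labels$subtype <- withr::with_seed(99, sample(perm_labels$subtype))
  feats <- feature_matrix(sim$expression, rownames(sim$expression)[1:8],
                          alpha = 0)
  m <- fast_cv_train(feats, perm_labels, "rf", seed = 15)
  expect_lt(abs(m$cv_accuracy - 0.2), 0.1) # 5 balanced classes
})

test_that("all four learners train and predict through the same interface", {
  sim <- quick_sim(n = 12, delta = 3, sigma = 0.5, seed = 18)
  feats <- feature_matrix(sim$expression, rownames(sim$expression)[1:8],
                          alpha = 0.05)
  for (algo in c("rf", "svm", "cart", "nb")) {
    m <- fast_cv_train(feats, sim$labels, algo, seed = 21)
    expect_s3_class(m, "miniabs_model")
    expect_true(m$cv_accuracy >= 0 && m$cv_accuracy <= 1)
    expect_identical(m$feature_names, colnames(feats))
    pred <- predict(m, sim$expression)
    expect_setequal(names(pred), c("sample_id", "subtype"))
    expect_true(all(pred$subtype %in% subtype_levels()))
  }
})

test_that("run_grid trains one row per configuration", {
  sim <- quick_sim(n = 10, delta = 3, sigma = 0.5, seed = 25)
  tab <- call_ssdegs(sim$expression, sim$labels,
                     gene_universe = rownames(sim$expression))
  grid <- run_grid(sim$expression, sim$labels, tab, seeds = seed_genes(),
                   levels = 1, algorithms = c("rf", "cart"),
                   alphas = c(0, 1), folds = 2, repeats = 1,
                   tune_grid_size = 1, seed = 30, ntree = 60)
  expect_equal(nrow(grid), 4L) # |levels| x |algorithms| x |alphas|
  expect_true(all(grid$cv_accuracy >= 0 & grid$cv_accuracy <= 1))
  expect_s3_class(grid$model[[1]], "miniabs_model")
  expect_error(run_grid(sim$expression, sim$labels, tab, algorithms = c()),
               "must not be empty")
})

test_that("initial-model selection prefers the smallest near-best level", {
  fake_grid <- tibble::tibble(
    level = 1:5,
    n_genes = c(8, 13, 18, 23, 28),
    algorithm = "rf", alpha = 0,
    cv_accuracy = c(0.834, 0.880, 0.879, 0.878, 0.877)
  )
  sel <- select_initial_model(fake_grid, tolerance = 0.005)
  expect_equal(sel$level, 2L)
  expect_equal(sel$row$cv_accuracy, 0.880)

  # all equal -> smallest set wins; zero tolerance + increasing -> last level
  flat <- dplyr::mutate(fake_grid, cv_accuracy = 0.9)
  expect_equal(select_initial_model(flat)$level, 1L)
  inc <- dplyr::mutate(fake_grid, cv_accuracy = 0.80 + 0.01 * level)
  expect_equal(select_initial_model(inc, tolerance = 0)$level, 5L)
})

test_that("accuracy ties break by algorithm preference then smaller alpha", {
  g <- tidyr::expand_grid(level = 1L, algorithm = c("nb", "svm", "rf"),
                          alpha = c(0.2, 0))
  g$cv_accuracy <- 0.9
  g$n_genes <- 8L
  sel <- select_initial_model(g)
  expect_equal(sel$row$algorithm, "rf")
  expect_equal(sel$row$alpha, 0)
})
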