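test_that("sequence identity and greedy clustering match the all-pairs oracle", {
  expect_equal(sequence_identity("AAAA", "AAAA"), 1)
  expect_equal(sequence_identity("AAAA", "AATT"), 0.5)
  expect_equal(sequence_identity("AAAA", "AATTGGGG"), 0.5)  # shorter-length convention

  # two families of five cloned pairs -> exactly two clusters
  ds <- generate_ppi_dataset(n_pairs = 10, variants_per_pair = 1, eps = 0,
                             seed = 5, n_families = 2, pairing = "diagonal")
  cl <- cluster_pairs(ds$triplets$interactor_id, ds$triplets$partner_id, ds$sequences)
  expect_equal(length(unique(cl)), 2L)
  concat <- paste0(ds$sequences[ds$triplets$interactor_id],
                   ds$sequences[ds$triplets$partner_id])
  oracle <- oracle_identity_components(concat)
  # identical partition up to relabeling
  expect_equal(length(unique(oracle)), length(unique(cl)))
  expect_true(all(tapply(oracle, cl, function(x) length(unique(x))) == 1))

  # identical pairs share a cluster; unrelated random sequences do not
  seqs <- c(X1 = "ACDEFGHIKLMNPQRS", X2 = "ACDEFGHIKLMNPQRS",
            Y1 = "WWYYTTRRGGHHKKLL", Y2 = "PPQQNNMMEEDDSSAA")
  cl2 <- cluster_pairs(c("X1", "Y1"), c("X2", "Y2"), seqs)
  expect_equal(length(unique(cl2)), 2L)
  cl3 <- cluster_pairs(c("X1", "X1"), c("X2", "X2"), seqs)
  expect_equal(length(unique(cl3)), 1L)
})

test_that("group k-fold keeps clusters intact and partitions all pairs", {
  clusters <- rep(1:10, times = c(8, 7, 6, 5, 5, 4, 3, 3, 2, 2))
  fold <- group_kfold(clusters, k = 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, length(clusters))
  for (cl in unique(clusters)) {
    expect_length(unique(fold[clusters == cl]), 1L)
  }
  # singleton clusters with k equal to cluster count: one per fold
  f1 <- group_kfold(1:10, k = 10, seed = 1)
  expect_equal(sort(tabulate(f1, 10)), rep(1L, 10))
  expect_identical(group_kfold(clusters, 5, seed = 3), fold)
  expect_error(group_kfold(rep(1:3, 4), k = 5), "cannot split")
})

test_that("test classes count shared proteins per the paired-input scheme", {
  train <- c("I1", "I2", "P1")
  expect_equal(assign_test_class("I1", "P1", train), 1L)
  expect_equal(assign_test_class("I1", "P9", train), 2L)
  expect_equal(assign_test_class("I9", "P1", train), 2L)
  expect_equal(assign_test_class("I9", "P9", train), 3L)
})

test_that("rank-based AUC matches the pair-counting oracle and is monotone-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(8)
  null_auc <- roc_auc(runif(4000), rep(0:1, 2000))
  expect_lt(abs(null_auc - 0.5), 0.03)

  scores <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.9)
  labels <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  for (seed in 1:3) {
    set.seed(seed)
    s <- sample(seq(0, 1, by = 0.05), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
    expect_equal(roc_auc(qlogis(pmin(pmax(s, 0.01), 0.99)), y), roc_auc(s, y))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "one class")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- rnorm(200)
  y <- as.integer(runif(200) < plogis(s))
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
})

test_that("fold AUCs aggregate as a size-weighted mean", {
  expect_equal(weighted_auc(c(0.8, 0.6), c(10, 30)), 0.65)
  expect_equal(weighted_auc(c(0.8, NA, 0.6), c(10, 99, 30)), 0.65)
})

test_that("cross-validation is leakage-free, class bins partition folds, and reruns identically", {
  ds <- generate_ppi_dataset(n_pairs = 18, variants_per_pair = 4, eps = 0, seed = 6,
                             n_families = 3)
  samples <- prepare_ppi_samples(ds$triplets, ds$sequences, ds$structures, tiny_embedder())
  cfg <- quick_config(epochs = 2, seed = 2, dropout = 0)
  cv <- run_cv(samples, ds$sequences, cfg, iterations = 2, k = 3,
               min_class_n = 5, seed = 21)
  # no cluster spans train and test in any fold
  for (it in seq_along(cv$assignments)) {
    fold_of <- cv$assignments[[it]]
    for (f in unique(fold_of)) {
      expect_length(intersect(cv$clusters[fold_of == f], cv$clusters[fold_of != f]), 0L)
    }
  }
  # class bins partition every test fold
  for (sc in cv$scores) {
    expect_length(sc$class, length(sc$idx))
    fr <- cv$folds[cv$folds$iteration == sc$iteration & cv$folds$fold == sc$fold, ]
    expect_equal(sum(fr$n), length(sc$idx))
  }
  # aggregate equals the size-weighted mean of the recorded fold AUCs
  for (cb in cv$aggregate$class) {
    sub <- cv$folds[cv$folds$class == cb, ]
    expect_equal(cv$aggregate$auc[cv$aggregate$class == cb],
                 weighted_auc(sub$auc, sub$n))
  }
  cv2 <- run_cv(samples, ds$sequences, cfg, iterations = 2, k = 3,
                min_class_n = 5, seed = 21)
  expect_identical(cv$folds, cv2$folds)
})

test_that("blind test excludes training variants and bins against the full training set", {
  tp <- tiny_ppi()
  train <- tp$samples[1:60]
  bench <- c(tp$samples[35:44], tp$samples[61:90])
  train_keys <- unique(vapply(train, function(s) paste(s$interactor_id, s$variant), character(1)))
  bench_keys <- vapply(bench, function(s) paste(s$interactor_id, s$variant), character(1))
  expected_excluded <- sum(bench_keys %in% train_keys)
  res <- blind_test(train, bench, tp$ds$sequences, quick_config(epochs = 1, seed = 4),
                    k = 3, seed = 5, min_class_n = 5)
  expect_equal(res$excluded, expected_excluded)
  expect_length(res$scores, length(bench) - expected_excluded)
  # a benchmark of only novel proteins is all class 3
  novel <- lapply(tp$samples[91:96], function(s) {
    s$interactor_id <- "ZZ1"; s$partner_id <- "ZZ2"; s
  })
  res2 <- blind_test(train, novel, tp$ds$sequences, quick_config(epochs = 1, seed = 4),
                     k = 3, seed = 5, min_class_n = 2)
  expect_true(all(res2$class == 3L))
  # a benchmark that is a copy of the training variants is fully excluded
  expect_error(blind_test(train, train, tp$ds$sequences, quick_config(epochs = 1), k = 3),
               "no benchmark pairs remain")
})

test_that("mean ROC curves interpolate the step function on a fixed grid", {
  sets <- list(list(scores = c(0.9, 0.8, 0.3, 0.2), labels = c(1, 1, 0, 0)),
               list(scores = c(0.9, 0.2, 0.8, 0.3), labels = c(1, 1, 0, 0)))
  sm <- roc_curve_summary(sets)
  expect_equal(nrow(sm), 101L)
  expect_equal(sm$tpr_mean[1], 0.75)  # perfect curve 1.0 + second curve 0.5 at fpr 0
  expect_equal(sm$tpr_mean[101], 1)
  expect_true(all(diff(sm$tpr_mean) >= -1e-12))
})
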