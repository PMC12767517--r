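test_that("forward output lies in (0,1), is deterministic, and checks roles/dims", {
  tp <- tiny_ppi()
  model <- tiny_model()
  probs <- predict_batch(model, tp$samples[1:10])
  expect_true(all(probs > 0 & probs < 1))
  expect_identical(probs, predict_batch(model, tp$samples[1:10]))

  s <- tp$samples[[1]]
  s_bad <- s
  s_bad$mut_node <- which(s$roles == "partner")[1]
  expect_error(predict_perturbation(model, s_bad), "partner chain")
  s_dim <- s
  s_dim$X <- cbind(s$X, 0)
  expect_error(predict_perturbation(model, s_dim), "dimension")
})

test_that("predictions are equivariant under node relabeling", {
  tp <- tiny_ppi()
  model <- tiny_model()
  s <- tp$samples[[3]]
  p0 <- predict_perturbation(model, s)
  set.seed(7)
  for (rep in 1:3) {
    perm <- sample(nrow(s$X))
    s2 <- s
    s2$X <- s$X[perm, ]
    s2$mask <- s$mask[perm, perm]
    s2$roles <- s$roles[perm]
    s2$mut_node <- which(perm == s$mut_node)
    expect_equal(predict_perturbation(model, s2), p0, tolerance = 1e-10)
  }
})

test_that("class weights are inverse-frequency normalized to balanced mean 1", {
  expect_equal(unname(compute_class_weights(c(0, 0, 1, 1))), c(1, 1))
  w <- compute_class_weights(c(rep(0, 90), rep(1, 10)))
  expect_equal(unname(w), c(100 / 180, 100 / 20))
  # combined-corpus label counts: 1395 disruptive, 4499 non-disruptive
  w2 <- compute_class_weights(c(rep("disruptive", 1395), rep("non-disruptive", 4499)))
  expect_equal(unname(w2["1"]), 5894 / (2 * 1395))
  expect_equal(unname(w2["0"]), 5894 / (2 * 4499))
  expect_error(compute_class_weights(rep(1, 5)), "both classes")
})

test_that("training is reproducible under a fixed seed and records its class weights", {
  tp <- tiny_ppi()
  cfg <- quick_config(epochs = 3, seed = 77)
  m1 <- finetune(NULL, cfg, tp$samples[1:40])
  m2 <- finetune(NULL, cfg, tp$samples[1:40])
  expect_identical(m1$report$train_loss, m2$report$train_loss)
  expect_identical(m1$params, m2$params)
  labels <- vapply(tp$samples[1:40], `[[`, numeric(1), "label")
  expect_equal(m1$report$class_weights, compute_class_weights(labels))
  expect_true(all(is.finite(m1$report$train_loss)))
  expect_error(finetune(NULL, cfg, list()), "empty dataset")
})

test_that("ensembles average member probabilities", {
  tp <- tiny_ppi()
  s <- tp$samples[[2]]
  models <- lapply(c(5, 6, 7), function(sd) finetune(NULL, quick_config(epochs = 1, seed = sd), tp$samples[1:30]))
  probs <- vapply(models, function(m) predict_perturbation(m, s), numeric(1))
  expect_equal(predict_ensemble(models, s), mean(probs))
  expect_equal(predict_ensemble(models[1], s), probs[1])
  expect_error(predict_ensemble(list(), s), "at least one")
})

test_that("model checkpoints round-trip bit-identically with stable checksums", {
  tp <- tiny_ppi()
  model <- tiny_model()
  p1 <- withr::local_tempfile(fileext = ".rds")
  p2 <- withr::local_tempfile(fileext = ".rds")
  save_model(model, p1)
  save_model(model, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  back <- load_model(p1)
  expect_identical(predict_batch(back, tp$samples[1:5]), predict_batch(model, tp$samples[1:5]))
  expect_error(load_model(p1, expect_dim = 99), "does not match expected dimension")
  saveRDS(list(format_version = 999L), p2)
  expect_error(load_model(p2), "format version")
})

test_that("pretraining recovers the planted buried-disrupts rule", {
  stab <- generate_stability_dataset(n_proteins = 20, variants_per_protein = 10,
                                    eps = 0, seed = 23)
  samples <- prepare_stability_samples(stab$records, stab$sequences, stab$structures,
                                       tiny_embedder(32))
  test_idx <- which(vapply(samples, `[[`, character(1), "interactor_id") %in%
                      sprintf("S%03d", 17:20))
  train_idx <- setdiff(seq_along(samples), test_idx)
  model <- pretrain_stability(quick_config(dim = 32, hidden = 64, epochs = 14, seed = 3),
                              samples[train_idx])
  expect_equal(model$stage, "pretrained")
  auc <- roc_auc(predict_batch(model, samples[test_idx]),
                 vapply(samples[test_idx], `[[`, numeric(1), "label"))
  expect_gte(auc, 0.9)
})

test_that("interface variants score higher than variants far from the interface", {
  tp <- tiny_ppi()
  model <- tiny_model()
  at_if <- tp$ds$triplets$at_interface
  probs <- predict_batch(model, tp$samples)
  expect_gt(mean(probs[at_if]), mean(probs[!at_if]))
})

test_that("stability pretraining accelerates fine-tuning on the interaction task", {
  ds <- generate_ppi_dataset(n_pairs = 12, variants_per_pair = 6, eps = 0, seed = 41)
  samples <- prepare_ppi_samples(ds$triplets, ds$sequences, ds$structures, tiny_embedder())
  stab <- generate_stability_dataset(n_proteins = 10, variants_per_protein = 8,
                                     eps = 0, seed = 42)
  ssamples <- prepare_stability_samples(stab$records, stab$sequences, stab$structures,
                                        tiny_embedder())
  target <- 0.5
  epochs_to_target <- function(m) {
    hit <- which(m$report$train_loss <= target)
    if (length(hit)) hit[1] else Inf
  }
  res <- vapply(1:5, function(sd) {
    pre <- pretrain_stability(quick_config(epochs = 6, seed = sd + 100), ssamples)
    cfg <- quick_config(epochs = 12, seed = sd)
    c(pre = epochs_to_target(finetune(pre, cfg, samples)),
      scratch = epochs_to_target(finetune(NULL, cfg, samples)))
  }, numeric(2))
  expect_lte(median(res["pre", ]), median(res["scratch", ]))
})
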