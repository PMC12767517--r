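#' Ungapped sequence identity (CD-HIT convention)
#'
#' Identical positions of the ungapped position-wise comparison divided by the
#' length of the shorter sequence.
#'
#' @param a,b Amino-acid strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  va <- strsplit(substr(a, 1L, n), "")[[1L]]
  vb <- strsplit(substr(b, 1L, n), "")[[1L]]
  sum(va == vb) / n
}

#' Cluster variant-partner pairs by concatenated wild-type sequences
#'
#' Greedy incremental clustering of the concatenation interactor+partner
#' sequence: sequences are sorted by length descending (ties broken
#' lexicographically for determinism); each joins the first existing cluster
#' whose representative it matches at `identity_threshold` or better
#' ([sequence_identity()]), else founds a new cluster. Pairs sharing both
#' proteins always share a cluster.
#'
#' @param interactor_id,partner_id Character vectors (one element per pair).
#' @param sequences Named character vector of wild-type sequences.
#' @param identity_threshold Identity threshold; default 0.5.
#' @return Integer vector of cluster ids, one per input pair.
#' @export
cluster_pairs <- function(interactor_id, partner_id, sequences, identity_threshold = 0.5) {
  concat <- vapply(seq_along(interactor_id), function(i) {
    si <- sequences[[interactor_id[i]]]
    sp <- sequences[[partner_id[i]]]
    if (is.null(si) || is.null(sp)) {
      stopf("missing sequence for '%s' or '%s'", interactor_id[i], partner_id[i])
    }
    paste0(si, sp)
  }, character(1))
  uniq <- unique(concat)
  uniq <- uniq[order(-nchar(uniq), uniq)]
  reps <- character(0)
  assign_of <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    hit <- 0L
    for (j in seq_along(reps)) {
      if (sequence_identity(uniq[i], reps[j]) >= identity_threshold) { hit <- j; break }
    }
    if (hit == 0L) {
      reps <- c(reps, uniq[i])
      hit <- length(reps)
    }
    assign_of[i] <- hit
  }
  assign_of[match(concat, uniq)]
}

#' Parse a CD-HIT .clstr file
#'
#' Optional adapter for runs where the external CD-HIT tool performed the
#' clustering; returns cluster ids keyed by sequence name.
#'
#' @param path Path to a `.clstr` file.
#' @return Named integer vector (sequence name -> cluster id).
#' @export
parse_clstr <- function(path) {
  lines <- readLines(path)
  cl <- cumsum(grepl("^>Cluster", lines))
  member <- !grepl("^>Cluster", lines)
  nm <- sub("^.*>", "", sub("\\.\\.\\..*$", "", lines[member]))
  stats::setNames(cl[member], nm)
}

#' Group k-fold partition over clusters
#'
#' Clusters are assigned whole to folds, greedily largest-first (by pair
#' count) into the currently lightest fold, so no cluster ever spans the
#' train/test split. The assignment depends only on (clusters, k, seed).
#'
#' @param clusters Integer vector of cluster ids, one per pair.
#' @param k Number of folds; default 10.
#' @param seed Integer seed (breaks ties among equally-sized clusters).
#' @return Integer vector of fold ids (1..k), one per pair.
#' @export
group_kfold <- function(clusters, k = 10L, seed = 1L) {
  ids <- unique(clusters)
  if (length(ids) < k) {
    stopf("cannot split %d clusters into %d folds", length(ids), k)
  }
  sizes <- as.integer(table(factor(clusters, levels = ids)))
  ord <- with_seed(seed, {
    shuffle <- sample(seq_along(ids))
    shuffle[order(-sizes[shuffle])]
  })
  load <- numeric(k)
  fold_of <- integer(length(ids))
  for (ci in ord) {
    f <- which.min(load)
    fold_of[ci] <- f
    load[f] <- load[f] + sizes[ci]
  }
  fold_of[match(clusters, ids)]
}

#' Park-Marcotte test class of a variant-partner pair
#'
#' Class 1: both proteins of the test pair appear among the training-pair
#' proteins; class 2: exactly one does; class 3: neither does.
#'
#' @param interactor_id,partner_id Character vectors (one element per test
#'   pair).
#' @param train_proteins Character vector of protein ids present in training.
#' @return Integer vector of classes in `{1, 2, 3}`.
#' @export
assign_test_class <- function(interactor_id, partner_id, train_proteins) {
  shared <- (interactor_id %in% train_proteins) + (partner_id %in% train_proteins)
  as.integer(3L - shared)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney statistic: tied scores contribute 1/2.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (1/0, TRUE/FALSE); both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels %in% c(1, TRUE, "1"))
  n1 <- sum(y)
  n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) stopf("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# tpr of the empirical ROC step function at the given fpr grid
roc_curve_points <- function(scores, labels, grid = seq(0, 1, length.out = 101L)) {
  y <- as.integer(labels %in% c(1, TRUE, "1"))
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord])
  fp <- cumsum(1 - y[ord])
  fpr <- c(0, fp / max(sum(1 - y), 1L))
  tpr <- c(0, tp / max(sum(y), 1L))
  vapply(grid, function(g) max(tpr[fpr <= g + 1e-12]), numeric(1))
}

#' Mean ROC curve across folds on a fixed FPR grid
#'
#' Vertical averaging over 101 equally spaced false-positive-rate points.
#'
#' @param score_sets List of lists with fields `scores` and `labels` (one per
#'   fold).
#' @param grid FPR grid.
#' @return Data frame with `fpr`, `tpr_mean`, `tpr_sem`.
#' @export
roc_curve_summary <- function(score_sets, grid = seq(0, 1, length.out = 101L)) {
  curves <- vapply(score_sets, function(s) roc_curve_points(s$scores, s$labels, grid),
                   numeric(length(grid)))
  curves <- matrix(curves, nrow = length(grid))
  data.frame(fpr = grid,
             tpr_mean = rowMeans(curves),
             tpr_sem = apply(curves, 1L, stats::sd) / sqrt(ncol(curves)))
}

#' Leakage-aware group cross-validation
#'
#' Repeats a 10-fold group cross-validation for several iterations: pairs are
#' clustered once by concatenated wild-type sequences; each iteration draws a
#' fresh seed-derived cluster-to-fold partition; per fold a model is trained
#' (optionally initialized from a pretrained model) on the training pairs and
#' evaluated on the held-out pairs, binned into Park-Marcotte classes against
#' that fold's training proteins. Per-class AUCs are aggregated as the mean
#' weighted by the number of test data points; class bins with fewer than
#' `min_class_n` points (or a single label class) are recorded but excluded
#' from the aggregate.
#'
#' @param samples Prepared labeled samples ([prepare_ppi_samples()]).
#' @param sequences Named character vector of wild-type sequences (for
#'   clustering).
#' @param config A [model_config] used for each fold model.
#' @param iterations Number of CV iterations; default 30.
#' @param k Folds per iteration; default 10.
#' @param min_class_n Minimum class-bin size entering the aggregate;
#'   default 30.
#' @param seed Master seed; the result is a deterministic function of
#'   (samples, config, iterations, k, seed).
#' @param pretrained Optional pretrained model used to initialize each fold
#'   model.
#' @param identity_threshold Clustering identity threshold; default 0.5.
#' @return Object of class `cv_result`: list with `folds` (data frame:
#'   iteration, fold, class, n, auc), `aggregate` (class, auc, n), `clusters`,
#'   `assignments` (per-iteration fold id per sample) and `scores`.
#' @export
run_cv <- function(samples, sequences, config, iterations = 30L, k = 10L,
                   min_class_n = 30L, seed = 1L, pretrained = NULL,
                   identity_threshold = 0.5) {
  labels <- vapply(samples, `[[`, numeric(1), "label")
  if (any(is.na(labels))) stopf("cross-validation requires labeled samples")
  i_id <- vapply(samples, `[[`, character(1), "interactor_id")
  p_id <- vapply(samples, `[[`, character(1), "partner_id")
  clusters <- cluster_pairs(i_id, p_id, sequences, identity_threshold)

  it_seeds <- derive_seeds(seed, iterations * (k + 1L))
  rows <- list()
  assignments <- vector("list", iterations)
  score_sets <- list()
  si <- 0L
  for (it in seq_len(iterations)) {
    si <- si + 1L
    fold_of <- group_kfold(clusters, k, seed = it_seeds[si])
    assignments[[it]] <- fold_of
    for (f in seq_len(k)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      if (length(test_idx) == 0L) next
      cfg <- config
      cfg$seed <- as.integer((config$seed + 7919 * it + 13 * f) %% 2147483647)
      model <- finetune(pretrained, cfg, samples[train_idx])
      scores <- predict_batch(model, samples[test_idx])
      train_proteins <- unique(c(i_id[train_idx], p_id[train_idx]))
      cls <- assign_test_class(i_id[test_idx], p_id[test_idx], train_proteins)
      score_sets[[length(score_sets) + 1L]] <-
        list(iteration = it, fold = f, scores = scores,
             labels = labels[test_idx], class = cls, idx = test_idx)
      for (cb in sort(unique(cls))) {
        in_bin <- cls == cb
        auc <- NA_real_
        if (sum(in_bin) >= min_class_n && length(unique(labels[test_idx][in_bin])) == 2L) {
          auc <- roc_auc(scores[in_bin], labels[test_idx][in_bin])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = it, fold = f, class = cb, n = sum(in_bin), auc = auc)
      }
    }
  }
  folds <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(sort(unique(folds$class)), function(cb) {
    sub <- folds[folds$class == cb & !is.na(folds$auc), , drop = FALSE]
    data.frame(class = cb,
               auc = if (nrow(sub)) sum(sub$auc * sub$n) / sum(sub$n) else NA_real_,
               n = sum(folds$n[folds$class == cb]))
  }))
  structure(list(folds = folds, aggregate = agg, clusters = clusters,
                 assignments = assignments, scores = score_sets,
                 iterations = iterations, k = k, min_class_n = min_class_n,
                 seed = seed),
            class = "cv_result")
}

#' Size-weighted mean of per-fold AUCs
#'
#' @param auc Numeric vector of fold AUCs.
#' @param n Integer vector of fold sizes.
#' @return `sum(auc * n) / sum(n)`.
#' @export
weighted_auc <- function(auc, n) {
  keep <- !is.na(auc)
  sum(auc[keep] * n[keep]) / sum(n[keep])
}

#' Blind-test evaluation with a fold-model ensemble
#'
#' Trains one model per group-CV fold of the training set and scores a
#' disjoint benchmark with the ensemble mean. Benchmark variants present in
#' the training data (same interactor and mutation, any partner) are excluded
#' before scoring; remaining pairs are binned into Park-Marcotte classes
#' against the FULL training protein set.
#'
#' @param train_samples,bench_samples Prepared samples.
#' @param sequences Named character vector covering the training proteins.
#' @param config A [model_config].
#' @param k Number of folds / ensemble members; default 10.
#' @param seed Master seed.
#' @param pretrained Optional pretrained initialization.
#' @param min_class_n Minimum class size for an AUC; default 30.
#' @inheritParams run_cv
#' @return List with `per_class` (class, n, auc), `scores`, `class`,
#'   `excluded` (count of benchmark pairs removed by the variant filter) and
#'   `kept_idx`.
#' @export
blind_test <- function(train_samples, bench_samples, sequences, config,
                       k = 10L, seed = 1L, pretrained = NULL, min_class_n = 30L,
                       identity_threshold = 0.5) {
  train_var <- unique(vapply(train_samples, function(s) paste(s$interactor_id, s$variant), character(1)))
  bench_var <- vapply(bench_samples, function(s) paste(s$interactor_id, s$variant), character(1))
  keep <- !(bench_var %in% train_var)
  excluded <- sum(!keep)
  if (!any(keep)) stopf("no benchmark pairs remain after excluding training variants")
  bench <- bench_samples[keep]

  i_id <- vapply(train_samples, `[[`, character(1), "interactor_id")
  p_id <- vapply(train_samples, `[[`, character(1), "partner_id")
  clusters <- cluster_pairs(i_id, p_id, sequences, identity_threshold)
  fold_of <- group_kfold(clusters, k, seed = seed)
  models <- lapply(seq_len(k), function(f) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + 13 * f) %% 2147483647)
    finetune(pretrained, cfg, train_samples[fold_of != f])
  })
  scores <- vapply(bench, function(s) predict_ensemble(models, s), numeric(1))
  labels <- vapply(bench, `[[`, numeric(1), "label")
  train_proteins <- unique(c(i_id, p_id))
  cls <- assign_test_class(vapply(bench, `[[`, character(1), "interactor_id"),
                           vapply(bench, `[[`, character(1), "partner_id"),
                           train_proteins)
  per_class <- do.call(rbind, lapply(sort(unique(cls)), function(cb) {
    in_bin <- cls == cb
    auc <- NA_real_
    if (sum(in_bin) >= min_class_n && length(unique(labels[in_bin])) == 2L) {
      auc <- roc_auc(scores[in_bin], labels[in_bin])
    }
    data.frame(class = cb, n = sum(in_bin), auc = auc)
  }))
  list(per_class = per_class, scores = scores, labels = labels, class = cls,
       excluded = excluded, kept_idx = which(keep), models = models)
}
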