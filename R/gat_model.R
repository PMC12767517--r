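#' Model configuration
#'
#' Architecture and optimization settings of the perturbation model: a stack
#' of graph-attention (GAT) layers over the residue contact graph (each node
#' also attends to itself), a 2-layer feed-forward mutation processor applied
#' to the normalized mutation encoding, and a 2-layer head mapping the
#' concatenation of the mutation-site node representation and the processed
#' encoding to a single logistic probability of interaction loss.
#'
#' @param dim Input embedding dimension D.
#' @param hidden Hidden dimension shared by all components (must be divisible
#'   by `heads`); default 128.
#' @param layers Number of GAT layers; default 2 (a 2-hop receptive field
#'   around the mutation site).
#' @param heads Attention heads per layer; default 4.
#' @param mp_hidden,head_hidden Hidden sizes of the mutation processor and the
#'   prediction head; default `hidden`.
#' @param dropout Dropout rate applied during training; default 0.2.
#' @param lr Adam learning rate (1e-3 for pretraining, 1e-4 for fine-tuning by
#'   convention of [pretrain_stability()] / [finetune()]).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param val_frac Fraction of the training samples held out for early
#'   stopping (used when the training set is large enough); default 0.1.
#' @param patience Early-stopping patience in epochs; default 10.
#' @param class_weight Use inverse-frequency class weights; default TRUE.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(dim, hidden = 128L, layers = 2L, heads = 4L,
                         mp_hidden = hidden, head_hidden = hidden,
                         dropout = 0.2, lr = 1e-3, epochs = 50L,
                         batch_size = 32L, val_frac = 0.1, patience = 10L,
                         class_weight = TRUE, seed = 1L) {
  stopifnot(dim >= 1, hidden >= 1, layers >= 1, heads >= 1,
            dropout >= 0, dropout < 1, lr > 0, epochs >= 1, batch_size >= 1)
  if (hidden %% heads != 0L) stopf("hidden (%d) must be divisible by heads (%d)", hidden, heads)
  structure(list(dim = as.integer(dim), hidden = as.integer(hidden),
                 layers = as.integer(layers), heads = as.integer(heads),
                 mp_hidden = as.integer(mp_hidden), head_hidden = as.integer(head_hidden),
                 dropout = dropout, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), val_frac = val_frac,
                 patience = as.integer(patience), class_weight = isTRUE(class_weight),
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# Flat named list of parameter arrays; initialization is seeded.
init_params <- function(config) {
  with_seed(config$seed, {
    p <- list()
    fan_in <- config$dim
    f <- config$hidden %/% config$heads
    for (l in seq_len(config$layers)) {
      for (h in seq_len(config$heads)) {
        tag <- sprintf("g%d_h%d", l, h)
        p[[paste0(tag, "_W")]] <- glorot(fan_in, f)
        p[[paste0(tag, "_as")]] <- as.numeric(glorot(f, 1L))
        p[[paste0(tag, "_ad")]] <- as.numeric(glorot(f, 1L))
      }
      fan_in <- config$hidden
    }
    p$mp_W1 <- glorot(config$dim, config$mp_hidden)
    p$mp_b1 <- numeric(config$mp_hidden)
    p$mp_W2 <- glorot(config$mp_hidden, config$hidden)
    p$mp_b2 <- numeric(config$hidden)
    p$hd_W1 <- glorot(2L * config$hidden, config$head_hidden)
    p$hd_b1 <- numeric(config$head_hidden)
    p$hd_W2 <- glorot(config$head_hidden, 1L)
    p$hd_b2 <- 0
    p
  })
}

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
relu <- function(x) pmax(x, 0)
leaky <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# Forward pass over one featured graph. `training` enables (seeded, caller-RNG)
# inverted dropout; the cache holds every intermediate needed by the backward
# pass.
gat_forward <- function(params, config, X, mask, mut_node, enc, training = FALSE) {
  if (ncol(X) != config$dim) {
    stopf("node feature dimension %d does not match model dimension %d", ncol(X), config$dim)
  }
  if (length(enc) != config$dim) {
    stopf("mutation encoding dimension %d does not match model dimension %d",
          length(enc), config$dim)
  }
  n <- nrow(X)
  f <- config$hidden %/% config$heads
  keep <- 1 - config$dropout
  drop_mask <- function(d) {
    if (training && config$dropout > 0) {
      (matrix(stats::runif(prod(d)), d[1L], d[2L]) < keep) / keep
    } else NULL
  }
  layers <- vector("list", config$layers)
  Xl <- X
  for (l in seq_len(config$layers)) {
    heads <- vector("list", config$heads)
    Z <- matrix(0, n, config$hidden)
    for (h in seq_len(config$heads)) {
      tag <- sprintf("g%d_h%d", l, h)
      H <- Xl %*% params[[paste0(tag, "_W")]]
      s <- as.numeric(H %*% params[[paste0(tag, "_as")]])
      t_ <- as.numeric(H %*% params[[paste0(tag, "_ad")]])
      E <- outer(s, t_, "+")
      E[!mask] <- -Inf
      L <- leaky(E)
      L[!mask] <- -Inf
      mx <- apply(L, 1L, max)
      A <- exp(L - mx)
      A[!mask] <- 0
      A <- A / rowSums(A)
      Zh <- A %*% H
      Z[, ((h - 1L) * f + 1L):(h * f)] <- Zh
      heads[[h]] <- list(H = H, E = E, A = A)
    }
    out <- elu(Z)
    dm <- drop_mask(dim(out))
    out_d <- if (is.null(dm)) out else out * dm
    layers[[l]] <- list(input = Xl, heads = heads, Z = Z, out = out, dmask = dm)
    Xl <- out_d
  }
  node_repr <- Xl[mut_node, ]

  a1 <- as.numeric(enc %*% params$mp_W1) + params$mp_b1
  r1 <- relu(a1)
  mp_dm <- if (training && config$dropout > 0) {
    (stats::runif(length(r1)) < keep) / keep
  } else NULL
  r1d <- if (is.null(mp_dm)) r1 else r1 * mp_dm
  m <- as.numeric(r1d %*% params$mp_W2) + params$mp_b2

  u <- c(node_repr, m)
  b1 <- as.numeric(u %*% params$hd_W1) + params$hd_b1
  h1 <- relu(b1)
  hd_dm <- if (training && config$dropout > 0) {
    (stats::runif(length(h1)) < keep) / keep
  } else NULL
  h1d <- if (is.null(hd_dm)) h1 else h1 * hd_dm
  logit <- sum(h1d * params$hd_W2) + params$hd_b2
  prob <- 1 / (1 + exp(-logit))

  list(prob = prob,
       cache = list(layers = layers, mut_node = mut_node, enc = enc,
                    a1 = a1, r1 = r1, r1d = r1d, mp_dm = mp_dm,
                    u = u, b1 = b1, h1 = h1, h1d = h1d, hd_dm = hd_dm,
                    mask = mask, n = n, f = f))
}

# Analytic gradients of the (already weighted) loss wrt every parameter, given
# d(loss)/d(logit).
gat_backward <- function(params, config, cache, dlogit) {
  g <- list()
  f <- cache$f
  # head
  g$hd_W2 <- matrix(dlogit * cache$h1d, ncol = 1L)
  g$hd_b2 <- dlogit
  dh1d <- dlogit * as.numeric(params$hd_W2)
  dh1 <- if (is.null(cache$hd_dm)) dh1d else dh1d * cache$hd_dm
  db1 <- dh1 * (cache$b1 > 0)
  g$hd_W1 <- outer(cache$u, db1)
  g$hd_b1 <- db1
  du <- as.numeric(params$hd_W1 %*% db1)
  hidden <- config$hidden
  dnode <- du[seq_len(hidden)]
  dm <- du[hidden + seq_len(hidden)]
  # mutation processor
  g$mp_W2 <- outer(cache$r1d, dm)
  g$mp_b2 <- dm
  dr1d <- as.numeric(params$mp_W2 %*% dm)
  dr1 <- if (is.null(cache$mp_dm)) dr1d else dr1d * cache$mp_dm
  da1 <- dr1 * (cache$a1 > 0)
  g$mp_W1 <- outer(cache$enc, da1)
  g$mp_b1 <- da1
  # GAT stack
  dOut_d <- matrix(0, cache$n, hidden)
  dOut_d[cache$mut_node, ] <- dnode
  for (l in rev(seq_len(config$layers))) {
    lay <- cache$layers[[l]]
    dOut <- if (is.null(lay$dmask)) dOut_d else dOut_d * lay$dmask
    dZ <- dOut * ifelse(lay$Z > 0, 1, exp(lay$Z))
    dXl <- matrix(0, cache$n, ncol(lay$input))
    for (h in seq_len(config$heads)) {
      tag <- sprintf("g%d_h%d", l, h)
      hc <- lay$heads[[h]]
      dZh <- dZ[, ((h - 1L) * f + 1L):(h * f), drop = FALSE]
      dA <- dZh %*% t(hc$H)
      dA[!cache$mask] <- 0
      dH <- t(hc$A) %*% dZh
      rs <- rowSums(hc$A * dA)
      dL <- hc$A * (dA - rs)
      dE <- dL * ifelse(hc$E > 0, 1, 0.2)
      dE[!cache$mask] <- 0
      ds <- rowSums(dE)
      dt_ <- colSums(dE)
      a_s <- params[[paste0(tag, "_as")]]
      a_d <- params[[paste0(tag, "_ad")]]
      dH <- dH + outer(ds, a_s) + outer(dt_, a_d)
      g[[paste0(tag, "_as")]] <- as.numeric(t(hc$H) %*% ds)
      g[[paste0(tag, "_ad")]] <- as.numeric(t(hc$H) %*% dt_)
      g[[paste0(tag, "_W")]] <- t(lay$input) %*% dH
      dXl <- dXl + dH %*% t(params[[paste0(tag, "_W")]])
    }
    dOut_d <- dXl
  }
  g
}

#' Inverse-frequency class weights
#'
#' `w_c = n / (2 * n_c)`, i.e. inverse class frequency normalized so the mean
#' weight over samples of a balanced dataset is 1.
#'
#' @param labels Vector of binary labels (0/1, logical, or a factor with two
#'   levels).
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
compute_class_weights <- function(labels) {
  y <- as.integer(labels %in% c(1, TRUE, "1", "disruptive", "disrupting"))
  n <- length(y)
  n1 <- sum(y)
  if (n1 == 0L || n1 == n) stopf("both classes must be present to compute class weights")
  c("0" = n / (2 * (n - n1)), "1" = n / (2 * n1))
}

sample_loss <- function(prob, y, w) {
  -w * (y * log(prob) + (1 - y) * log(1 - prob))
}

# Core trainer shared by pretraining and fine-tuning. `samples` is a list of
# prepared samples (fields X, mask, roles, enc_raw, mut_node, label); the
# encoding normalizer is fitted here on the training samples only.
train_gat <- function(samples, config, init = NULL, stage = "finetuned") {
  if (length(samples) == 0L) stopf("cannot train on an empty dataset")
  labels <- vapply(samples, `[[`, numeric(1), "label")
  if (any(is.na(labels))) stopf("all training samples must be labeled")
  weights <- if (config$class_weight) compute_class_weights(labels) else c("0" = 1, "1" = 1)

  norm <- fit_normalizer(lapply(samples, `[[`, "enc_raw"))
  encs <- lapply(samples, function(s) normalize_encoding(s$enc_raw, norm))

  params <- init %||% init_params(config)
  adam_m <- lapply(params, function(x) x * 0)
  adam_v <- lapply(params, function(x) x * 0)
  adam_t <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  with_seed(config$seed, {
    n <- length(samples)
    n_val <- if (n >= 30L) max(3L, round(config$val_frac * n)) else 0L
    val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    best <- params
    best_val <- Inf
    wait <- 0L
    train_losses <- numeric(0)
    val_losses <- numeric(0)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample(tr_idx)
      ep_loss <- 0
      for (start in seq(1L, length(perm), by = config$batch_size)) {
        batch <- perm[start:min(start + config$batch_size - 1L, length(perm))]
        grads <- NULL
        for (i in batch) {
          s <- samples[[i]]
          fw <- gat_forward(params, config, s$X, s$mask, s$mut_node, encs[[i]], training = TRUE)
          y <- labels[i]
          w <- weights[[as.character(y)]]
          ep_loss <- ep_loss + sample_loss(fw$prob, y, w)
          g <- gat_backward(params, config, fw$cache, w * (fw$prob - y))
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        scale <- 1 / length(batch)
        adam_t <- adam_t + 1L
        for (nm in names(params)) {
          gr <- grads[[nm]] * scale
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr * gr
          mhat <- adam_m[[nm]] / (1 - b1^adam_t)
          vhat <- adam_v[[nm]] / (1 - b2^adam_t)
          params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
        }
      }
      train_losses <- c(train_losses, ep_loss / length(tr_idx))
      if (n_val > 0L) {
        vl <- 0
        for (i in val_idx) {
          s <- samples[[i]]
          fw <- gat_forward(params, config, s$X, s$mask, s$mut_node, encs[[i]])
          vl <- vl + sample_loss(fw$prob, labels[i], weights[[as.character(labels[i])]])
        }
        vl <- vl / n_val
        val_losses <- c(val_losses, vl)
        if (vl < best_val - 1e-9) {
          best_val <- vl
          best <- params
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      } else {
        best <- params
      }
    }
    if (n_val == 0L) best <- params
    structure(
      list(params = best, config = config, stage = stage, normalizer = norm,
           report = list(train_loss = train_losses, val_loss = val_losses,
                         final_epoch = length(train_losses),
                         class_weights = weights, seed = config$seed)),
      class = "perturbation_model")
  })
}

#' Pretrain on stability labels
#'
#' Stage one of the two-stage protocol: the model is trained to separate
#' stability-preserving from stability-disrupting variants on monomer contact
#' graphs (single chain, intra-chain contacts, same 4.5 Angstrom rule), with
#' class-weighted binary cross-entropy. The binary head is shared with the
#' fine-tuning stage (disrupting aligned with interaction-lost).
#'
#' @param config A [model_config] (its `lr` is used as given; default 1e-3).
#' @param samples Prepared monomer samples from [prepare_stability_samples()].
#' @return A `perturbation_model` tagged `"pretrained"`.
#' @export
pretrain_stability <- function(config, samples) {
  train_gat(samples, config, stage = "pretrained")
}

#' Fine-tune on interaction-perturbation labels
#'
#' Stage two: all parameters (no freezing) are updated on labeled
#' variant-partner triplets with class-weighted binary cross-entropy.
#'
#' @param model A pretrained `perturbation_model`, or `NULL` to train from
#'   scratch (ablation).
#' @param config A [model_config]; conventionally with a smaller learning rate
#'   (1e-4) when starting from a pretrained model.
#' @param samples Prepared complex samples from [prepare_ppi_samples()].
#' @return A `perturbation_model` tagged `"finetuned"`.
#' @export
finetune <- function(model, config, samples) {
  init <- NULL
  if (!is.null(model)) {
    stopifnot(inherits(model, "perturbation_model"))
    if (model$config$dim != config$dim || model$config$hidden != config$hidden ||
        model$config$layers != config$layers || model$config$heads != config$heads) {
      stopf("pretrained model architecture does not match the fine-tuning config")
    }
    init <- model$params
  }
  train_gat(samples, config, init = init, stage = "finetuned")
}

#' Predict the interaction-loss probability for one prepared sample
#'
#' The sample's raw mutation encoding is normalized with the model's own
#' (training-fitted) normalizer; the mutation-site node must lie on the
#' interactor chain (flip roles upstream otherwise).
#'
#' @param model A `perturbation_model`.
#' @param sample A prepared sample (fields `X`, `mask`, `roles`, `enc_raw`,
#'   `mut_node`).
#' @return Probability in (0, 1).
#' @export
predict_perturbation <- function(model, sample) {
  stopifnot(inherits(model, "perturbation_model"))
  if (!is.null(sample$roles) && sample$roles[sample$mut_node] != "interactor") {
    stopf("mutation node lies on the partner chain; flip the complex roles first")
  }
  enc <- normalize_encoding(sample$enc_raw, model$normalizer)
  gat_forward(model$params, model$config, sample$X, sample$mask, sample$mut_node, enc)$prob
}

#' @rdname predict_perturbation
#' @param samples List of prepared samples.
#' @return `predict_batch` returns a numeric vector of probabilities.
#' @export
predict_batch <- function(model, samples) {
  vapply(samples, function(s) predict_perturbation(model, s), numeric(1))
}

#' Average predictions over an ensemble of models
#'
#' @param models Non-empty list of `perturbation_model`s with identical
#'   dimensionality (e.g. one per cross-validation fold).
#' @param sample A prepared sample.
#' @return Arithmetic mean of the member probabilities.
#' @export
predict_ensemble <- function(models, sample) {
  if (length(models) == 0L) stopf("ensemble must contain at least one model")
  dims <- vapply(models, function(m) m$config$dim, integer(1))
  if (length(unique(dims)) != 1L) stopf("ensemble members have differing dimensionality")
  mean(vapply(models, function(m) predict_perturbation(m, sample), numeric(1)))
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a perturbation model
#'
#' The checkpoint embeds the configuration, the training-stage tag, the
#' encoding normalizer and a format version; loading a checkpoint with a
#' different format version, or against an expected dimension that does not
#' match, is a compatibility error. Round-tripping preserves outputs
#' bit-identically.
#'
#' @param model A `perturbation_model`.
#' @param path Checkpoint file path.
#' @param expect_dim Optional input dimension the caller requires.
#' @return `load_model` returns the `perturbation_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "perturbation_model"))
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, expect_dim = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stopf("'%s' is not a compatible model checkpoint (format version mismatch)", path)
  }
  model <- structure(obj$model, class = "perturbation_model")
  if (!is.null(expect_dim) && model$config$dim != expect_dim) {
    stopf("model dimension %d does not match expected dimension %d",
          model$config$dim, expect_dim)
  }
  model
}
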