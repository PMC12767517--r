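test_that("apply_mutation substitutes exactly one residue and is an involution", {
  spec <- mutation_spec("X", 3, "D", "G")
  expect_equal(apply_mutation("ACDEF", spec), "ACGEF")
  back <- mutation_spec("X", 3, "G", "D")
  expect_equal(apply_mutation(apply_mutation("ACDEF", spec), back), "ACDEF")
  expect_error(apply_mutation("ACDEF", mutation_spec("X", 3, "E", "G")), "reference mismatch")
  expect_error(apply_mutation("ACDEF", mutation_spec("X", 9, "D", "G")), "out of range")
  expect_error(mutation_spec("X", 2, "A", "A"), "must differ")
})

test_that("raw mutation encoding is the row difference at the variant site", {
  wt <- matrix(c(1, 2, 3, 5), 2, 2, byrow = TRUE)
  mut <- matrix(c(1, 2, 6, 8), 2, 2, byrow = TRUE)
  expect_equal(encode_mutation_raw(wt, mut, 1), c(0, 0))
  expect_equal(encode_mutation_raw(wt, mut, 2), c(3, 3))
  expect_error(encode_mutation_raw(wt, mut[1, , drop = FALSE], 1), "shape mismatch")
  set.seed(5)
  a <- matrix(rnorm(40), 8, 5); b <- matrix(rnorm(40), 8, 5)
  for (p in c(1, 4, 8)) expect_equal(encode_mutation_raw(a, b, p), b[p, ] - a[p, ])
})

test_that("normalizer uses population sd, maps zero-variance dimensions to 0", {
  norm <- fit_normalizer(rbind(c(0), c(2)))
  # mean 1, population sd 1, so 0 maps to -1
  expect_equal(as.numeric(normalize_encoding(0, norm)), -1)

  set.seed(2)
  raw <- matrix(rnorm(60, mean = 3, sd = 2), 20, 3)
  raw[, 3] <- 7  # constant dimension
  nz <- fit_normalizer(raw)
  z <- t(apply(raw, 1, normalize_encoding, normalizer = nz))
  expect_equal(colMeans(z), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z[, 1:2], 2, function(x) sqrt(mean((x - mean(x))^2)))),
               c(1, 1), tolerance = 1e-9)
  expect_true(all(z[, 3] == 0))
  expect_true(nz$zero_variance[3])
  expect_error(fit_normalizer(rbind(c(1, 2))), "at least 2")

  # idempotence: re-fitting on normalized encodings gives mean ~0, sd ~1
  nz2 <- fit_normalizer(z)
  expect_equal(unname(nz2$mean[1:2]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(nz2$sd[1:2]), c(1, 1), tolerance = 1e-9)
})

test_that("synthetic embedder is deterministic, seed-sensitive and local", {
  emb <- synthetic_embedder(8, seed = 3, window = 1)
  expect_identical(emb$embed("ACD"), emb$embed("ACD"))
  expect_false(identical(emb$embed("ACD"), synthetic_embedder(8, seed = 4)$embed("ACD")))
  m1 <- emb$embed("ACDEFG")
  m2 <- emb$embed("ACNEFG")  # substitution at position 3, window 1
  changed <- which(rowSums(abs(m1 - m2)) > 0)
  expect_equal(changed, 2:4)
  # embedding must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(emb$embed("ACDEFG")); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("node features map chain embeddings onto the graph by position", {
  cx <- generate_complex(3, 2, patch = 1, seed = 6)
  g <- build_contact_graph(cx)
  emb_i <- matrix(1:6 * 1.0, 3, 2)
  emb_p <- matrix(101:104 * 1.0, 2, 2)
  X <- build_node_features(g, emb_i, emb_p)
  for (n in seq_len(nrow(g$nodes))) {
    src <- if (g$nodes$chain_role[n] == "interactor") emb_i else emb_p
    expect_equal(X[n, ], src[g$nodes$position[n], ])
  }
  # swapping roles swaps the feature source
  Xf <- build_node_features(build_contact_graph(flip_roles(cx)), emb_p, emb_i)
  expect_equal(Xf[1:2, ], emb_p)
  expect_error(build_node_features(g, emb_i[1:2, ], emb_p), "interactor embedding")
})

test_that("mutant features differ from wild-type only near the variant site", {
  emb <- tiny_embedder(8)
  seqs <- "LKAVDEWKRN"
  spec <- mutation_spec("X", 5, "D", "R")
  wt <- emb$embed(seqs)
  mut <- emb$embed(apply_mutation(seqs, spec))
  cx <- generate_complex(10, 4, patch = 2, seed = 8)
  g <- build_contact_graph(cx)
  pe <- emb$embed("AAAA")
  X_wt <- build_node_features(g, wt, pe)
  X_mut <- build_node_features(g, mut, pe)
  changed <- which(rowSums(abs(X_wt - X_mut)) > 0)
  expect_equal(changed, 4:6)  # window 1 around position 5 on the interactor chain
})

test_that("embedding cache round-trips through the precomputed embedder", {
  emb <- tiny_embedder(6)
  cache <- embedding_cache()
  m <- embed_cached(emb, "ACDEF", cache)
  expect_identical(embed_cached(emb, "ACDEF", cache), m)
  path <- withr::local_tempfile(fileext = ".rds")
  save_embedding_cache(cache, path)
  pre <- make_embedder("precomputed", path = path)
  expect_identical(pre$embed("ACDEF"), m)
  expect_error(pre$embed("GGGG"), "no precomputed embedding")
})
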