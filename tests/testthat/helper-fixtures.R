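# Shared fixtures, built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# hand-written 3+2-residue two-chain PDB, with hydrogens and an altloc pair
write_tiny_pdb <- function(path, with_hydrogens = FALSE) {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   0.500   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA ALEU A   3       7.600   0.000   0.000  0.40  0.00           C",
    "ATOM      5  CA BLEU A   3       7.700   0.000   0.000  0.60  0.00           C",
    "ATOM      6  CA  LYS B   1       0.000   4.200   0.000  1.00  0.00           C",
    "ATOM      7  CA  TRP B   2       3.800   4.200   0.000  1.00  0.00           C")
  if (with_hydrogens) {
    lines <- c(lines,
      "ATOM      8  H   ALA A   1       0.500   0.100   0.100  1.00  0.00           H",
      "ATOM      9  H   LYS B   1       0.100   4.300   0.100  1.00  0.00           H")
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}

quick_config <- function(dim = 16, hidden = 32, epochs = 3, seed = 1, dropout = 0.1, ...) {
  model_config(dim = dim, hidden = hidden, heads = 4, epochs = epochs,
               lr = 1e-3, dropout = dropout, seed = seed, ...)
}

tiny_embedder <- function(dim = 16) synthetic_embedder(dim, seed = 11, window = 1)

# small planted PPI dataset + prepared samples, reused by model tests
tiny_ppi <- function() memo("tiny_ppi", {
  ds <- generate_ppi_dataset(n_pairs = 16, variants_per_pair = 6, eps = 0,
                             seed = 31, n_families = 3)
  samples <- prepare_ppi_samples(ds$triplets, ds$sequences, ds$structures, tiny_embedder())
  list(ds = ds, samples = samples)
})

# a trained model on the tiny dataset
tiny_model <- function() memo("tiny_model", {
  tp <- tiny_ppi()
  finetune(NULL, quick_config(epochs = 8), tp$samples)
})
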