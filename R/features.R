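#' Missense variant specification
#'
#' @param interactor_id Identifier of the mutated protein.
#' @param position 1-based position on the wild-type sequence.
#' @param wt_aa,mut_aa One-letter wild-type and mutant amino acids (must differ).
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(interactor_id, position, wt_aa, mut_aa) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stopf("position must be a positive integer")
  if (identical(wt_aa, mut_aa)) stopf("wild-type and mutant amino acids must differ")
  structure(list(interactor_id = interactor_id, position = position,
                 wt_aa = wt_aa, mut_aa = mut_aa),
            class = "mutation_spec")
}

#' Parse a protein variant string such as "p.C61G" or "C61G"
#'
#' @param x Character vector of variant strings.
#' @param interactor_id Protein identifier(s) to attach (recycled).
#' @return A list of [mutation_spec] objects.
#' @export
parse_variant <- function(x, interactor_id = NA_character_) {
  interactor_id <- rep_len(interactor_id, length(x))
  m <- regmatches(x, regexec("^(?:p\\.)?([A-Za-z])([0-9]+)([A-Za-z])$", x))
  Map(function(mm, id, raw) {
    if (length(mm) != 4L) stopf("cannot parse variant '%s'", raw)
    mutation_spec(id, as.integer(mm[3L]), toupper(mm[2L]), toupper(mm[4L]))
  }, m, interactor_id, x)
}

format_variant <- function(spec) {
  sprintf("%s%d%s", spec$wt_aa, spec$position, spec$mut_aa)
}

#' Apply a missense variant to a sequence
#'
#' @param sequence Amino-acid string.
#' @param spec A [mutation_spec]; `spec$wt_aa` must match the sequence at
#'   `spec$position`.
#' @return The mutant sequence.
#' @export
apply_mutation <- function(sequence, spec) {
  n <- nchar(sequence)
  if (spec$position > n) {
    stopf("variant position %d out of range for sequence of length %d", spec$position, n)
  }
  ref <- substr(sequence, spec$position, spec$position)
  if (ref != spec$wt_aa) {
    stopf("reference mismatch at position %d: sequence has '%s', variant expects '%s'",
          spec$position, ref, spec$wt_aa)
  }
  paste0(substr(sequence, 1L, spec$position - 1L), spec$mut_aa,
         substr(sequence, spec$position + 1L, n))
}

#' Construct an embedder
#'
#' An embedder maps an amino-acid sequence to an L x D matrix of per-residue
#' vectors, deterministically (identical input gives bit-identical output).
#' Two kinds are provided: `"synthetic"` (a seeded, local-context hash
#' embedder used throughout testing) and `"precomputed"` (per-residue matrices
#' computed elsewhere, e.g. by ProtT5, and stored in a keyed cache file).
#'
#' @param name `"synthetic"` or `"precomputed"`.
#' @param dimension Embedding dimension D (synthetic only; default 32).
#' @param seed Integer seed for the synthetic embedder.
#' @param window Local context half-width of the synthetic embedder: the row at
#'   position k depends on residues k-window..k+window only, so a point
#'   mutation perturbs only rows within that window.
#' @param path Cache file (RDS keyed by sequence) for `"precomputed"`.
#' @return An object of class `embedder` with fields `name`, `dimension` and
#'   `embed(sequence)`.
#' @export
make_embedder <- function(name = c("synthetic", "precomputed"),
                          dimension = 32L, seed = 1L, window = 1L, path = NULL) {
  name <- match.arg(name)
  if (name == "synthetic") {
    if (dimension < 2L) stopf("embedding dimension must be >= 2")
    synthetic_embedder(dimension, seed, window)
  } else {
    if (is.null(path)) stopf("precomputed embedder requires a cache path")
    precomputed_embedder(path)
  }
}

#' @rdname make_embedder
#' @export
synthetic_embedder <- function(dimension = 32L, seed = 1L, window = 1L) {
  dimension <- as.integer(dimension)
  if (dimension < 2L) stopf("embedding dimension must be >= 2")
  force(seed); force(window)
  # row k = base vector of the residue identity + a smaller local-context
  # term hashed from the k-mer around k. The shared per-amino-acid base makes
  # residue identity a consistent, learnable direction across sequences (as in
  # real pLM embeddings), while the context term carries the locality
  # property: a substitution perturbs only rows within the window.
  context_scale <- 0.25
  embed <- function(sequence) {
    L <- nchar(sequence)
    if (L == 0L) stopf("cannot embed an empty sequence")
    padded <- paste0(strrep("^", window), sequence, strrep("$", window))
    out <- matrix(0, L, dimension)
    for (k in seq_len(L)) {
      aa <- substr(sequence, k, k)
      ctx <- substr(padded, k, k + 2L * window)
      h_aa <- (hash_string(aa) + 1299721 * (seed %% 65536)) %% 2147483629
      h_ctx <- (hash_string(ctx) + 2654435761 * (seed %% 65536)) %% 2147483629
      out[k, ] <- with_seed(h_aa, stats::rnorm(dimension)) +
        context_scale * with_seed(h_ctx, stats::rnorm(dimension))
    }
    out
  }
  structure(list(name = "synthetic", dimension = dimension, seed = seed,
                 window = window, embed = embed),
            class = "embedder")
}

precomputed_embedder <- function(path) {
  if (!file.exists(path)) stopf("embedding cache not found: %s", path)
  store <- readRDS(path)
  if (!is.list(store) || is.null(names(store))) stopf("'%s' is not a keyed embedding cache", path)
  dimension <- ncol(store[[1L]])
  embed <- function(sequence) {
    m <- store[[sequence]]
    if (is.null(m)) stopf("no precomputed embedding for sequence of length %d", nchar(sequence))
    m
  }
  structure(list(name = "precomputed", dimension = dimension, path = path, embed = embed),
            class = "embedder")
}

#' Embedding cache
#'
#' In-memory cache keyed by sequence, avoiding repeated embedding of the same
#' sequence. [save_embedding_cache()] persists it as a keyed RDS container
#' usable by the `"precomputed"` embedder.
#'
#' @param embedder An [make_embedder] object.
#' @param sequence Amino-acid string.
#' @param cache Environment created by `embedding_cache()`.
#' @return `embed_cached` returns the L x D matrix.
#' @export
embedding_cache <- function() new.env(parent = emptyenv())

#' @rdname embedding_cache
#' @export
embed_cached <- function(embedder, sequence, cache) {
  key <- sequence
  if (!is.null(cache[[key]])) return(cache[[key]])
  m <- embedder$embed(sequence)
  cache[[key]] <- m
  m
}

#' @rdname embedding_cache
#' @param path Output RDS path.
#' @export
save_embedding_cache <- function(cache, path) {
  saveRDS(as.list(cache), path)
  invisible(path)
}

#' Raw mutation encoding
#'
#' The difference between the mutant and wild-type per-residue embeddings at
#' the variant position.
#'
#' @param wt_emb,mut_emb L x D embedding matrices of the wild-type and mutant
#'   interactor sequences.
#' @param position 1-based variant position.
#' @return Numeric D-vector `mut_emb[position, ] - wt_emb[position, ]`.
#' @export
encode_mutation_raw <- function(wt_emb, mut_emb, position) {
  if (!all(dim(wt_emb) == dim(mut_emb))) {
    stopf("embedding shape mismatch: %dx%d vs %dx%d",
          nrow(wt_emb), ncol(wt_emb), nrow(mut_emb), ncol(mut_emb))
  }
  if (position < 1L || position > nrow(wt_emb)) {
    stopf("position %d out of range 1..%d", position, nrow(wt_emb))
  }
  mut_emb[position, ] - wt_emb[position, ]
}

#' Z-score normalizer over a set of raw mutation encodings
#'
#' Fitted on the training variants only and applied frozen to test encodings.
#' Uses the population standard deviation (divide by n); dimensions with zero
#' variance are flagged and map to 0.
#'
#' @param raw_encodings Numeric matrix (variants x D) or list of D-vectors;
#'   at least two encodings are required.
#' @return An object of class `encoding_normalizer` with `mean`, `sd` and
#'   `zero_variance` (logical per dimension).
#' @export
fit_normalizer <- function(raw_encodings) {
  if (is.list(raw_encodings)) raw_encodings <- do.call(rbind, raw_encodings)
  if (!is.matrix(raw_encodings) || nrow(raw_encodings) < 2L) {
    stopf("need at least 2 encodings to fit a normalizer")
  }
  mu <- colMeans(raw_encodings)
  centered <- sweep(raw_encodings, 2L, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  zero <- sd_pop < 1e-12
  structure(list(mean = mu, sd = sd_pop, zero_variance = zero),
            class = "encoding_normalizer")
}

#' @rdname fit_normalizer
#' @param enc Numeric D-vector (a raw encoding).
#' @param normalizer A fitted `encoding_normalizer`.
#' @return `normalize_encoding` returns the z-scored D-vector (zero-variance
#'   dimensions are 0), with attribute `normalized = TRUE`.
#' @export
normalize_encoding <- function(enc, normalizer) {
  stopifnot(inherits(normalizer, "encoding_normalizer"))
  if (length(enc) != length(normalizer$mean)) {
    stopf("encoding dimension %d does not match normalizer dimension %d",
          length(enc), length(normalizer$mean))
  }
  out <- (enc - normalizer$mean) / ifelse(normalizer$zero_variance, 1, normalizer$sd)
  out[normalizer$zero_variance] <- 0
  attr(out, "normalized") <- TRUE
  out
}

#' Attach node features to a contact graph
#'
#' Interactor-role nodes receive rows of the MUTANT interactor embedding;
#' partner-role nodes receive rows of the wild-type partner embedding; mapping
#' is by within-chain position. For variants on the partner chain, flip the
#' complex roles upstream ([flip_roles()]) before calling.
#'
#' @param graph A `contact_graph`.
#' @param interactor_mut_emb L_i x D embedding of the mutant interactor
#'   sequence.
#' @param partner_wt_emb L_p x D embedding of the wild-type partner sequence
#'   (omit for monomer graphs).
#' @return N x D numeric matrix of node features, rows ordered by node index.
#' @export
build_node_features <- function(graph, interactor_mut_emb, partner_wt_emb = NULL) {
  stopifnot(inherits(graph, "contact_graph"))
  roles <- graph$nodes$chain_role
  n_i <- sum(roles == "interactor")
  n_p <- sum(roles == "partner")
  if (nrow(interactor_mut_emb) != n_i) {
    stopf("interactor embedding has %d rows but graph has %d interactor nodes",
          nrow(interactor_mut_emb), n_i)
  }
  if (n_p > 0L) {
    if (is.null(partner_wt_emb)) stopf("graph has partner nodes but no partner embedding given")
    if (nrow(partner_wt_emb) != n_p) {
      stopf("partner embedding has %d rows but graph has %d partner nodes",
            nrow(partner_wt_emb), n_p)
    }
    if (ncol(partner_wt_emb) != ncol(interactor_mut_emb)) {
      stopf("embedding dimensions differ between chains")
    }
  }
  X <- matrix(0, nrow(graph$nodes), ncol(interactor_mut_emb))
  X[roles == "interactor", ] <- interactor_mut_emb[graph$nodes$position[roles == "interactor"], , drop = FALSE]
  if (n_p > 0L) {
    X[roles == "partner", ] <- partner_wt_emb[graph$nodes$position[roles == "partner"], , drop = FALSE]
  }
  X
}
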