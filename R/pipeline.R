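pair_id <- function(interactor_id, partner_id) paste(interactor_id, partner_id, sep = "::")

#' Prepare model samples for variant-partner triplets
#'
#' For every triplet, builds (or reuses) the complex contact graph, embeds the
#' mutant interactor and wild-type partner sequences, maps the embeddings onto
#' the graph as node features and computes the raw mutation encoding
#' (mutant minus wild-type row at the variant site). Embeddings are cached by
#' sequence; graphs are cached per protein pair.
#'
#' @param triplets Data frame with columns `interactor_id`, `partner_id`,
#'   `wt_aa`, `position`, `mut_aa` and optionally `label`
#'   (`disruptive` / `non-disruptive`) — see [read_triplets()].
#' @param sequences Named character vector of wild-type sequences keyed by
#'   protein id.
#' @param structures Named list of [complex_structure] or `contact_graph`
#'   objects keyed by `"<interactor_id>::<partner_id>"`.
#' @param embedder An [make_embedder()] object.
#' @param threshold Contact threshold in Angstrom (used when `structures`
#'   holds raw complexes); default 4.5.
#' @return List of prepared samples; each has `X`, `mask`, `roles`, `enc_raw`,
#'   `mut_node`, `label` (1 = disruptive, 0 = non-disruptive, NA = unlabeled),
#'   `interactor_id`, `partner_id`, `variant` and `pair`.
#' @export
prepare_ppi_samples <- function(triplets, sequences, structures, embedder, threshold = 4.5) {
  emb_cache <- embedding_cache()
  graph_cache <- new.env(parent = emptyenv())
  get_graph <- function(pid) {
    if (!is.null(graph_cache[[pid]])) return(graph_cache[[pid]])
    obj <- structures[[pid]]
    if (is.null(obj)) stopf("no structure for protein pair '%s'", pid)
    g <- if (inherits(obj, "contact_graph")) obj else build_contact_graph(obj, threshold)
    graph_cache[[pid]] <- list(graph = g, mask = graph_mask(g))
    graph_cache[[pid]]
  }
  lapply(seq_len(nrow(triplets)), function(r) {
    row <- triplets[r, ]
    pid <- pair_id(row$interactor_id, row$partner_id)
    gm <- get_graph(pid)
    seq_i <- sequences[[row$interactor_id]]
    seq_p <- sequences[[row$partner_id]]
    if (is.null(seq_i) || is.null(seq_p)) {
      stopf("missing sequence for '%s' or '%s'", row$interactor_id, row$partner_id)
    }
    spec <- mutation_spec(row$interactor_id, row$position, row$wt_aa, row$mut_aa)
    seq_mut <- apply_mutation(seq_i, spec)
    wt_emb <- embed_cached(embedder, seq_i, emb_cache)
    mut_emb <- embed_cached(embedder, seq_mut, emb_cache)
    p_emb <- embed_cached(embedder, seq_p, emb_cache)
    X <- build_node_features(gm$graph, mut_emb, p_emb)
    roles <- gm$graph$nodes$chain_role
    mut_node <- which(roles == "interactor" & gm$graph$nodes$position == spec$position)
    if (length(mut_node) != 1L) {
      stopf("variant position %d not found on the interactor chain of pair '%s'",
            spec$position, pid)
    }
    label <- if (is.null(row$label) || is.na(row$label)) NA_real_
             else as.numeric(row$label %in% c("disruptive", "1", 1, TRUE))
    list(X = X, mask = gm$mask, roles = roles,
         enc_raw = encode_mutation_raw(wt_emb, mut_emb, spec$position),
         mut_node = mut_node, label = label,
         interactor_id = row$interactor_id, partner_id = row$partner_id,
         variant = format_variant(spec), pair = pid)
  })
}

#' Prepare monomer samples for stability records
#'
#' Monomer graphs use the same contact rule (single chain, intra-chain edges
#' only); node features are rows of the mutant embedding and the label is 1
#' for stability-disrupting, 0 for stability-preserving. Records labeled
#' `excluded` (0.5 <= |ddG| < 1.5) are dropped.
#'
#' @param stability Data frame as returned by [read_stability()].
#' @param sequences Named character vector keyed by protein id.
#' @param structures Named list of [chain_structure] or `contact_graph`
#'   objects keyed by protein id.
#' @inheritParams prepare_ppi_samples
#' @return List of prepared samples (same fields as [prepare_ppi_samples()],
#'   without partner information).
#' @export
prepare_stability_samples <- function(stability, sequences, structures, embedder, threshold = 4.5) {
  stability <- stability[stability$label != "excluded", , drop = FALSE]
  emb_cache <- embedding_cache()
  graph_cache <- new.env(parent = emptyenv())
  get_graph <- function(id) {
    if (!is.null(graph_cache[[id]])) return(graph_cache[[id]])
    obj <- structures[[id]]
    if (is.null(obj)) stopf("no structure for protein '%s'", id)
    g <- if (inherits(obj, "contact_graph")) obj else build_contact_graph(obj, threshold)
    graph_cache[[id]] <- list(graph = g, mask = graph_mask(g))
    graph_cache[[id]]
  }
  lapply(seq_len(nrow(stability)), function(r) {
    row <- stability[r, ]
    gm <- get_graph(row$protein_id)
    seq_wt <- sequences[[row$protein_id]]
    if (is.null(seq_wt)) stopf("missing sequence for '%s'", row$protein_id)
    spec <- mutation_spec(row$protein_id, row$position, row$wt_aa, row$mut_aa)
    seq_mut <- apply_mutation(seq_wt, spec)
    wt_emb <- embed_cached(embedder, seq_wt, emb_cache)
    mut_emb <- embed_cached(embedder, seq_mut, emb_cache)
    X <- build_node_features(gm$graph, mut_emb)
    list(X = X, mask = gm$mask, roles = gm$graph$nodes$chain_role,
         enc_raw = encode_mutation_raw(wt_emb, mut_emb, spec$position),
         mut_node = spec$position, label = as.numeric(row$label == "disrupting"),
         interactor_id = row$protein_id, partner_id = NA_character_,
         variant = format_variant(spec), pair = row$protein_id)
  })
}
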