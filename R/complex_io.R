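#' Chain structure
#'
#' A single protein chain reduced to its heavy-atom coordinates, one entry per
#' residue. Residues are renumbered sequentially from 1 in file order (author
#' numbering gaps are ignored), so variant positions index the chain sequence
#' directly.
#'
#' @param chain_id Chain identifier (single string).
#' @param aa Character vector of one-letter amino-acid codes (non-standard
#'   residues are `"X"`).
#' @param atoms List (one element per residue) of numeric matrices with columns
#'   `x`, `y`, `z` and row names giving element symbols; hydrogens/deuteriums
#'   must already be absent.
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, aa, atoms) {
  if (length(aa) != length(atoms)) {
    stopf("chain '%s': %d residues but %d atom sets", chain_id, length(aa), length(atoms))
  }
  n_atoms <- vapply(atoms, nrow, integer(1))
  if (any(n_atoms < 1L)) {
    stopf("chain '%s': residues without heavy atoms at positions %s",
          chain_id, paste(which(n_atoms < 1L), collapse = ", "))
  }
  structure(
    list(chain_id = chain_id, aa = aa, atoms = atoms),
    class = "chain_structure"
  )
}

#' @export
length.chain_structure <- function(x) length(x$aa)

#' Two-chain complex with explicit interactor/partner roles
#'
#' @param interactor,partner [chain_structure] objects; `interactor` is the
#'   protein carrying the variant, `partner` its binding partner.
#' @param source_tag Free-text provenance tag.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(interactor, partner, source_tag = "") {
  stopifnot(inherits(interactor, "chain_structure"), inherits(partner, "chain_structure"))
  structure(
    list(interactor = interactor, partner = partner, source_tag = source_tag),
    class = "complex_structure"
  )
}

# map three-letter residue names to one letter; unknowns -> "X"
residue_one_letter <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% LETTERS] <- "X"
  out
}

#' Parse a two-chain complex from a PDB or mmCIF file
#'
#' Reads the named chains, strips hydrogens and deuteriums, resolves alternate
#' locations to the highest-occupancy conformer (ties broken by altloc
#' identifier order), drops HETATM records (waters, ligands) and renumbers
#' residues 1..L per chain. Residues lacking coordinates are omitted with a
#' warning.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param interactor_chain,partner_chain Chain identifiers to assign to the
#'   interactor (mutated protein) and partner roles.
#' @param source_tag Optional provenance tag stored on the result.
#' @return A [complex_structure].
#' @export
parse_complex <- function(path, interactor_chain, partner_chain, source_tag = NULL) {
  if (!file.exists(path)) stopf("structure file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stopf("cannot parse structure file '%s': %s", path, conditionMessage(e))
  )
  atom <- parsed$atom
  chains <- lapply(c(interactor_chain, partner_chain), function(ch) {
    extract_chain(atom, ch, path)
  })
  complex_structure(chains[[1L]], chains[[2L]],
                    source_tag = source_tag %||% basename(path))
}

extract_chain <- function(atom, chain_id, path) {
  rows <- atom[atom$chain %in% chain_id & atom$type == "ATOM", , drop = FALSE]
  if (nrow(rows) == 0L) {
    stopf("chain '%s' not found in '%s'", chain_id, path)
  }
  elesy <- rows$elesy
  if (is.null(elesy) || all(is.na(elesy))) {
    elesy <- substr(gsub("[^A-Za-z].*$", "", trimws(rows$elety)), 1L, 1L)
  }
  elesy <- toupper(trimws(elesy))
  keep <- !(elesy %in% c("H", "D"))
  rows <- rows[keep, , drop = FALSE]
  elesy <- elesy[keep]

  ins <- rows$insert
  ins[is.na(ins)] <- ""
  res_key <- paste(rows$resno, ins, sep = "_")
  res_order <- unique(res_key)

  aa <- character(0)
  atoms <- list()
  dropped <- 0L
  for (key in res_order) {
    ri <- which(res_key == key)
    sub <- rows[ri, , drop = FALSE]
    el <- elesy[ri]
    # altloc: per atom name keep the highest-occupancy conformer, ties by altloc order
    alt <- sub$alt
    alt[is.na(alt)] <- ""
    occ <- sub$o
    occ[is.na(occ)] <- 1
    pick <- unlist(lapply(split(seq_len(nrow(sub)), trimws(sub$elety)), function(ii) {
      ii[order(-occ[ii], alt[ii])][1L]
    }), use.names = FALSE)
    pick <- sort(pick)
    sub <- sub[pick, , drop = FALSE]
    el <- el[pick]
    xyz <- cbind(x = sub$x, y = sub$y, z = sub$z)
    ok <- stats::complete.cases(xyz)
    if (!any(ok)) {
      dropped <- dropped + 1L
      next
    }
    xyz <- xyz[ok, , drop = FALSE]
    rownames(xyz) <- el[ok]
    aa <- c(aa, residue_one_letter(sub$resid[1L]))
    atoms <- c(atoms, list(xyz))
  }
  if (dropped > 0L) {
    warnf("chain '%s': omitted %d residue(s) lacking coordinates", chain_id, dropped)
  }
  if (length(aa) == 0L) stopf("chain '%s' has no residues with coordinates", chain_id)
  chain_structure(chain_id, aa, atoms)
}

#' Build the residue contact graph of a two-chain complex
#'
#' Residues (across both chains) become nodes; an edge joins two distinct
#' residues when the minimum distance over all heavy-atom pairs is less than or
#' equal to `threshold` (a distance of exactly `threshold` counts as a
#' contact). Both intra- and inter-chain contacts are included; there are no
#' self-edges.
#'
#' @param complex A [complex_structure] (or a single [chain_structure] for
#'   monomer graphs).
#' @param threshold Contact distance threshold in Angstrom; default 4.5.
#' @return An object of class `contact_graph`: a list with `nodes` (data frame
#'   with columns `index`, `chain_role`, `position`, `aa`), `edges` (two-column
#'   integer matrix of node indices, first column < second) and
#'   `contact_threshold`.
#' @export
build_contact_graph <- function(complex, threshold = 4.5) {
  stopifnot(threshold > 0)
  if (inherits(complex, "chain_structure")) {
    chains <- list(interactor = complex)
  } else {
    stopifnot(inherits(complex, "complex_structure"))
    chains <- list(interactor = complex$interactor, partner = complex$partner)
  }
  lens <- vapply(chains, length, integer(1))
  if (any(lens == 0L)) stopf("degenerate input: empty chain")

  nodes <- data.frame(
    index = seq_len(sum(lens)),
    chain_role = rep(names(chains), lens),
    position = unlist(lapply(lens, seq_len), use.names = FALSE),
    aa = unlist(lapply(chains, `[[`, "aa"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  atoms <- do.call(c, lapply(chains, `[[`, "atoms"))
  n <- length(atoms)
  thr2 <- threshold * threshold
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    ai <- atoms[[i]]
    for (j in seq.int(i + 1L, n)) {
      aj <- atoms[[j]]
      dx <- outer(ai[, 1L], aj[, 1L], "-")
      dy <- outer(ai[, 2L], aj[, 2L], "-")
      dz <- outer(ai[, 3L], aj[, 3L], "-")
      if (min(dx * dx + dy * dy + dz * dz) <= thr2) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  structure(
    list(nodes = nodes,
         edges = cbind(from = from, to = to),
         contact_threshold = threshold),
    class = "contact_graph"
  )
}

#' Nodes participating in at least one inter-chain contact
#'
#' @param graph A [build_contact_graph] result.
#' @return Sorted integer vector of node indices incident to an edge whose two
#'   endpoints lie on different chains.
#' @export
interface_nodes <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  if (nrow(graph$edges) == 0L) return(integer(0))
  role <- graph$nodes$chain_role
  inter <- role[graph$edges[, 1L]] != role[graph$edges[, 2L]]
  sort(unique(as.integer(graph$edges[inter, , drop = FALSE])))
}

# dense logical adjacency with self-loops, used by the attention layers
graph_mask <- function(graph) {
  n <- nrow(graph$nodes)
  m <- diag(n) > 0
  if (nrow(graph$edges) > 0L) {
    m[graph$edges] <- TRUE
    m[graph$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  m
}

#' Serialize / read a contact graph as plain text
#'
#' The format is a header line `# contact_graph threshold=<t>`, one `node` line
#' per residue (`node index chain_role position aa`) and one `edge` line per
#' contact (`edge from to`).
#'
#' @param graph A `contact_graph`.
#' @param path Output (or input) file path.
#' @return `write_contact_graph` returns `path` invisibly; `read_contact_graph`
#'   returns a `contact_graph`.
#' @export
write_contact_graph <- function(graph, path) {
  stopifnot(inherits(graph, "contact_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contact_graph threshold=%.17g", graph$contact_threshold), con)
  writeLines(sprintf("node\t%d\t%s\t%d\t%s", graph$nodes$index,
                     graph$nodes$chain_role, graph$nodes$position, graph$nodes$aa), con)
  if (nrow(graph$edges) > 0L) {
    writeLines(sprintf("edge\t%d\t%d", graph$edges[, 1L], graph$edges[, 2L]), con)
  }
  invisible(path)
}

#' @rdname write_contact_graph
#' @export
read_contact_graph <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# contact_graph threshold=", lines[1L])) {
    stopf("'%s' is not a contact-graph file", path)
  }
  threshold <- as.numeric(sub("^# contact_graph threshold=", "", lines[1L]))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  kinds <- vapply(body, `[[`, character(1), 1L)
  nd <- body[kinds == "node"]
  nodes <- data.frame(
    index = as.integer(vapply(nd, `[[`, character(1), 2L)),
    chain_role = vapply(nd, `[[`, character(1), 3L),
    position = as.integer(vapply(nd, `[[`, character(1), 4L)),
    aa = vapply(nd, `[[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
  ed <- body[kinds == "edge"]
  edges <- if (length(ed)) {
    cbind(from = as.integer(vapply(ed, `[[`, character(1), 2L)),
          to = as.integer(vapply(ed, `[[`, character(1), 3L)))
  } else {
    cbind(from = integer(0), to = integer(0))
  }
  structure(list(nodes = nodes, edges = edges, contact_threshold = threshold),
            class = "contact_graph")
}

#' Chain sequences of a complex
#'
#' @param complex A [complex_structure].
#' @return Named character vector with elements `interactor` and `partner`.
#' @export
complex_sequences <- function(complex) {
  c(interactor = paste(complex$interactor$aa, collapse = ""),
    partner = paste(complex$partner$aa, collapse = ""))
}

#' Swap the interactor/partner roles of a complex
#'
#' Used when the variant lies on the partner chain: the model contract is
#' single-directional (variant on the interactor), so callers flip roles before
#' featurization.
#'
#' @param complex A [complex_structure].
#' @return A [complex_structure] with the two chains exchanged.
#' @export
flip_roles <- function(complex) {
  complex_structure(complex$partner, complex$interactor, source_tag = complex$source_tag)
}
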