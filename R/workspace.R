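aa_three <- function(aa) {
  out <- suppressWarnings(bio3d::aa123(aa))
  out[is.na(out) | nchar(out) != 3L] <- "UNK"
  out
}

# Minimal PDB ATOM-record writer for synthetic structures (CA / CB / CG
# pseudo-atoms, all carbon). Readable by any PDB parser.
write_pdb_chain_lines <- function(chain, chain_id, serial0) {
  lines <- character(0)
  serial <- serial0
  names3 <- c("CA", "CB", "CG", "CD", "CE")
  res3 <- aa_three(chain$aa)
  for (j in seq_along(chain$aa)) {
    xyz <- chain$atoms[[j]]
    for (a in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-2s  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, names3[a], res3[j], chain_id, j,
        xyz[a, 1L], xyz[a, 2L], xyz[a, 3L], 1, 0, rownames(xyz)[a]))
    }
  }
  list(lines = lines, serial = serial)
}

#' Write a synthetic structure as a PDB file
#'
#' @param x A [complex_structure] (chains written as A and B) or a
#'   [chain_structure] (chain A).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "complex_structure")) {
    a <- write_pdb_chain_lines(x$interactor, "A", 0L)
    b <- write_pdb_chain_lines(x$partner, "B", a$serial)
    lines <- c(a$lines, "TER", b$lines, "TER", "END")
  } else {
    a <- write_pdb_chain_lines(x, "A", 0L)
    lines <- c(a$lines, "TER", "END")
  }
  writeLines(lines, path)
  invisible(path)
}

parse_chain <- function(path, chain_id) {
  parsed <- bio3d::read.pdb(path, verbose = FALSE)
  extract_chain(parsed$atom, chain_id, path)
}

#' Emit a complete synthetic fixture workspace
#'
#' Writes, under `dir`: `structures/` (two-chain PDB per protein pair),
#' `monomers/` (single-chain PDB per stability protein), `sequences.fasta`,
#' `triplets.tsv`, `stability.tsv`, and a simulated edgotype scenario
#' (`scenario_predictions.tsv`, `scenario_strata.tsv`,
#' `scenario_partner_counts.tsv`). Everything is deterministic per seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param n_pairs,variants_per_pair,eps,chain_len,patch Passed to
#'   [generate_ppi_dataset()].
#' @param n_proteins,variants_per_protein Passed to
#'   [generate_stability_dataset()].
#' @param scenario Strata specification for [generate_edgotype_scenario()];
#'   a default two-stratum-plus-baseline scenario is used when `NULL`.
#' @return Invisible list of written paths.
#' @export
make_fixture_workspace <- function(dir, seed = 1L, n_pairs = 12L, variants_per_pair = 6L,
                                   eps = 0.05, chain_len = 15L, patch = 3L,
                                   n_proteins = 8L, variants_per_protein = 8L,
                                   scenario = NULL) {
  dir.create(file.path(dir, "structures"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "monomers"), showWarnings = FALSE)
  seeds <- derive_seeds(seed, 3L)
  ppi <- generate_ppi_dataset(n_pairs, variants_per_pair, eps = eps, seed = seeds[1L],
                              patch = patch)
  stab <- generate_stability_dataset(n_proteins, variants_per_protein, eps = eps,
                                     seed = seeds[2L], chain_len = chain_len)
  scenario <- scenario %||% list(
    pathogenic = list(qn = 0.45, edgetic = 0.35, n = 120L),
    benign = list(qn = 0.05, edgetic = 0.10, n = 120L),
    population = list(qn = 0.10, edgetic = 0.15, n = 200L))
  profiles <- generate_edgotype_scenario(scenario, seed = seeds[3L])

  paths <- list()
  for (pid in names(ppi$structures)) {
    p <- file.path(dir, "structures", paste0(gsub("::", "_", pid), ".pdb"))
    write_pdb(ppi$structures[[pid]], p)
    paths$structures <- c(paths$structures, p)
  }
  for (id in names(stab$structures)) {
    p <- file.path(dir, "monomers", paste0(id, ".pdb"))
    write_pdb(stab$structures[[id]], p)
    paths$monomers <- c(paths$monomers, p)
  }
  paths$fasta <- file.path(dir, "sequences.fasta")
  write_fasta_sequences(c(ppi$sequences, stab$sequences), paths$fasta)
  paths$triplets <- file.path(dir, "triplets.tsv")
  write_triplets(ppi$triplets, paths$triplets)
  paths$stability <- file.path(dir, "stability.tsv")
  st <- ppi_round_df(data.frame(protein_id = stab$records$protein_id,
                                variant = stab$records$variant,
                                ddG = stab$records$ddG, stringsAsFactors = FALSE))
  utils::write.table(st, paths$stability, sep = "\t", quote = FALSE, row.names = FALSE)

  pred <- list(); strat <- list(); cnt <- list()
  for (nm in names(profiles)) {
    for (pf in profiles[[nm]]) {
      pred[[length(pred) + 1L]] <- data.frame(
        interactor_id = pf$interactor_id, variant = pf$variant,
        partner_id = pf$partner_ids, prob = pf$probs, stringsAsFactors = FALSE)
      strat[[length(strat) + 1L]] <- data.frame(
        interactor_id = pf$interactor_id, variant = pf$variant, stratum = nm,
        stringsAsFactors = FALSE)
      cnt[[length(cnt) + 1L]] <- data.frame(
        interactor_id = pf$interactor_id, variant = pf$variant,
        available_partners = pf$available_partners, stringsAsFactors = FALSE)
    }
  }
  paths$scenario_predictions <- file.path(dir, "scenario_predictions.tsv")
  utils::write.table(ppi_round_df(do.call(rbind, pred)), paths$scenario_predictions,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$scenario_strata <- file.path(dir, "scenario_strata.tsv")
  utils::write.table(do.call(rbind, strat), paths$scenario_strata,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$scenario_partner_counts <- file.path(dir, "scenario_partner_counts.tsv")
  utils::write.table(do.call(rbind, cnt), paths$scenario_partner_counts,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# stable text formatting for numeric TSV columns
ppi_round_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.10g", df[[nm]])
  }
  df
}

#' Load a fixture workspace from disk
#'
#' Re-reads the files written by [make_fixture_workspace()] (or any files in
#' the same layout), parsing structures back from PDB.
#'
#' @param dir Workspace directory.
#' @return List with `sequences`, `triplets`, `stability`, `structures`
#'   (complexes keyed `"I::P"`) and `monomers` (chains keyed by protein id).
#' @export
load_workspace <- function(dir) {
  sequences <- read_fasta_sequences(file.path(dir, "sequences.fasta"))
  triplets <- read_triplets(file.path(dir, "triplets.tsv"))
  stability_path <- file.path(dir, "stability.tsv")
  stability <- if (file.exists(stability_path)) read_stability(stability_path) else NULL
  structures <- list()
  for (p in list.files(file.path(dir, "structures"), pattern = "\\.pdb$", full.names = TRUE)) {
    pid <- sub("_", "::", tools::file_path_sans_ext(basename(p)))
    structures[[pid]] <- parse_complex(p, "A", "B")
  }
  monomers <- list()
  for (p in list.files(file.path(dir, "monomers"), pattern = "\\.pdb$", full.names = TRUE)) {
    monomers[[tools::file_path_sans_ext(basename(p))]] <- parse_chain(p, "A")
  }
  list(sequences = sequences, triplets = triplets, stability = stability,
       structures = structures, monomers = monomers)
}

#' Read variant profiles from per-pair prediction tables
#'
#' @param predictions_path TSV with columns `interactor_id`, `variant`,
#'   `partner_id`, `prob`.
#' @param counts_path Optional TSV with columns `interactor_id`, `variant`,
#'   `available_partners`.
#' @return Named list of [variant_profile]s keyed `"interactor_id|variant"`.
#' @export
read_profiles <- function(predictions_path, counts_path = NULL) {
  df <- utils::read.delim(predictions_path, stringsAsFactors = FALSE)
  need <- c("interactor_id", "variant", "partner_id", "prob")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("prediction table lacks column(s): %s", paste(missing, collapse = ", "))
  counts <- NULL
  if (!is.null(counts_path)) {
    cdf <- utils::read.delim(counts_path, stringsAsFactors = FALSE)
    counts <- stats::setNames(cdf$available_partners, paste(cdf$interactor_id, cdf$variant, sep = "|"))
  }
  keys <- paste(df$interactor_id, df$variant, sep = "|")
  out <- lapply(split(seq_len(nrow(df)), keys), function(ii) {
    key <- keys[ii[1L]]
    variant_profile(df$interactor_id[ii[1L]], df$variant[ii[1L]],
                    df$partner_id[ii], df$prob[ii],
                    available_partners = if (!is.null(counts) && !is.na(counts[key]))
                      counts[[key]] else length(ii))
  })
  out[order(names(out))]
}
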