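#' Label a stability record from its ddG value
#'
#' Variants are stability-preserving when |ddG| < 0.5 kcal/mol and
#' stability-disrupting when |ddG| >= 1.5 kcal/mol (boundary inclusive);
#' anything in between is excluded from pretraining. The rule depends on the
#' magnitude only, so it is an even function of ddG.
#'
#' @param ddg Numeric vector of ddG values in kcal/mol.
#' @return Character vector with values `"preserving"`, `"disrupting"` or
#'   `"excluded"`.
#' @export
label_stability <- function(ddg) {
  if (!is.numeric(ddg) || any(!is.finite(ddg))) stopf("ddG values must be finite numbers")
  a <- abs(ddg)
  ifelse(a < 0.5, "preserving", ifelse(a >= 1.5, "disrupting", "excluded"))
}

triplet_key <- function(records) {
  paste(records$interactor_id, records$wt_aa, records$position,
        records$mut_aa, records$partner_id, sep = "|")
}

variant_key <- function(records) {
  paste(records$interactor_id, records$wt_aa, records$position, records$mut_aa, sep = "|")
}

#' Clean a triplet dataset
#'
#' Applies the dataset hygiene rules: records flagged as failed structure
#' generation are removed; identity keys carrying conflicting labels are
#' removed entirely (across sources); exact duplicates (same key, same label)
#' are collapsed to one. The identity key is
#' (interactor_id, wt_aa, position, mut_aa, partner_id).
#'
#' @param records Data frame with columns `interactor_id`, `position`,
#'   `wt_aa`, `mut_aa`, `partner_id`, `label` and optionally
#'   `structure_failed` (logical) and `source`.
#' @return List with `records` (the cleaned data frame) and `report`, a named
#'   integer vector with `kept`, `duplicates`, `conflicts` and
#'   `structure_failed` satisfying input = kept + duplicates + conflicts +
#'   structure_failed.
#' @export
clean_dataset <- function(records) {
  n_in <- nrow(records)
  if (is.null(records$structure_failed)) records$structure_failed <- FALSE
  records$structure_failed[is.na(records$structure_failed)] <- FALSE

  failed <- records$structure_failed
  n_failed <- sum(failed)
  records <- records[!failed, , drop = FALSE]

  key <- triplet_key(records)
  n_labels <- vapply(split(records$label, key), function(l) length(unique(l)), integer(1))
  conflict_keys <- names(n_labels)[n_labels > 1L]
  is_conflict <- key %in% conflict_keys
  n_conflict <- sum(is_conflict)
  records <- records[!is_conflict, , drop = FALSE]
  key <- key[!is_conflict]

  dup <- duplicated(key)
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL

  if (nrow(records) == 0L && n_in > 0L) warnf("cleaning removed every record")
  list(records = records,
       report = c(kept = nrow(records), duplicates = n_dup,
                  conflicts = n_conflict, structure_failed = n_failed))
}

triplet_columns <- c("interactor_id", "partner_id", "variant", "label")

#' Read / write variant-partner triplet tables
#'
#' TSV schema: columns `interactor_id`, `partner_id`, `variant` (e.g.
#' `p.C61G`), `label` (`disruptive`, `non-disruptive`, or empty for
#' unlabeled), and optionally `source` and `structure_failed` (0/1). Both LF
#' and CRLF line endings are accepted. Malformed rows raise an error naming
#' the offending line.
#'
#' @param path TSV file path.
#' @return Data frame with the variant expanded into `wt_aa`, `position`,
#'   `mut_aa` columns.
#' @export
read_triplets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(triplet_columns, names(df))
  if (length(missing)) {
    stopf("triplet table '%s' lacks required column(s): %s", path, paste(missing, collapse = ", "))
  }
  expand_variants(df, path)
}

expand_variants <- function(df, path) {
  m <- regexec("^(?:p\\.)?([A-Za-z])([0-9]+)([A-Za-z])$", df$variant)
  parts <- regmatches(df$variant, m)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stopf("malformed variant '%s' in '%s' at data line %d",
          df$variant[bad[1L]], path, bad[1L])
  }
  df$wt_aa <- toupper(vapply(parts, `[[`, character(1), 2L))
  df$position <- as.integer(vapply(parts, `[[`, character(1), 3L))
  df$mut_aa <- toupper(vapply(parts, `[[`, character(1), 4L))
  if (!is.null(df$structure_failed)) df$structure_failed <- df$structure_failed %in% c(1, "1", TRUE, "TRUE")
  if (!is.null(df$label)) df$label[df$label == ""] <- NA_character_
  df
}

#' @rdname read_triplets
#' @param records Data frame as returned by [read_triplets()] (the expanded
#'   columns are recombined into `variant`).
#' @export
write_triplets <- function(records, path) {
  out <- records
  if (is.null(out$variant)) {
    out$variant <- sprintf("p.%s%d%s", out$wt_aa, out$position, out$mut_aa)
  }
  keep <- intersect(c(triplet_columns, "source", "structure_failed"), names(out))
  utils::write.table(out[keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stability table
#'
#' TSV schema: `protein_id`, `variant`, `ddG` (kcal/mol, signed).
#'
#' @param path TSV file path.
#' @return Data frame with `protein_id`, `wt_aa`, `position`, `mut_aa`, `ddG`
#'   and a `label` column from [label_stability()].
#' @export
read_stability <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("protein_id", "variant", "ddG"), names(df))
  if (length(missing)) {
    stopf("stability table '%s' lacks required column(s): %s", path, paste(missing, collapse = ", "))
  }
  if (!is.numeric(df$ddG)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$ddG))))[1L]
    stopf("non-numeric ddG '%s' in '%s' at data line %d", df$ddG[bad], path, bad)
  }
  df <- expand_variants(df, path)
  df$label <- label_stability(df$ddG)
  df
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences keyed by record identifier.
#' @export
read_fasta_sequences <- function(path) {
  fa <- bio3d::read.fasta(path)
  seqs <- apply(fa$ali, 1L, function(r) paste(r[r != "-"], collapse = ""))
  names(seqs) <- sub("\\s.*$", "", rownames(fa$ali))
  toupper(seqs)
}

#' @rdname read_fasta_sequences
#' @param sequences Named character vector.
#' @export
write_fasta_sequences <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(c(paste0(">", id), sequences[[id]]), con)
  }
  invisible(path)
}
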