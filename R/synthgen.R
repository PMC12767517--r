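# Amino-acid alphabets used to plant a compositional interface/core signal:
# interface patches and buried cores draw from the hydrophobic set, everything
# else from the complementary set, emulating the compositional bias of real
# interfaces and making the planted disruption rules learnable from
# embeddings + graph structure alone.
AA_HYDRO <- c("I", "L", "V", "F", "W", "M", "Y")
AA_POLAR <- c("A", "C", "D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T")
AA_ALL <- c(AA_HYDRO, AA_POLAR)

# one chain laid out along the x axis: CA at 3.8 Angstrom spacing plus a
# pseudo side-chain atom pointing away from the partner; designated patch
# residues get an extra atom reaching toward the interface plane.
synth_chain <- function(chain_id, aa, x0, y_ca, y_side, y_iface, patch_pos, jitter) {
  n <- length(aa)
  atoms <- lapply(seq_len(n), function(j) {
    x <- x0 + 3.8 * j
    coords <- rbind(c(x, y_ca, 0), c(x, y_side, 0.3))
    rn <- c("C", "C")
    if (j %in% patch_pos) {
      coords <- rbind(coords, c(x, y_iface, 0))
      rn <- c(rn, "C")
    }
    coords <- coords + jitter[[j]][seq_len(nrow(coords)), , drop = FALSE]
    colnames(coords) <- c("x", "y", "z")
    rownames(coords) <- rn
    coords
  })
  chain_structure(chain_id, aa, atoms)
}

#' Generate a synthetic two-chain complex with a designed interface
#'
#' Both chains run along the x axis on opposite sides of an interface plane.
#' The central contiguous patches (aligned across chains) carry an extra atom
#' each, placed so that paired patch atoms are ~4.3 Angstrom apart (a contact
#' at the 4.5 Angstrom rule) while every non-patch residue stays more than 6
#' Angstrom from the other chain, making the planted interface unambiguous.
#' Coordinates receive a small seeded jitter and are bit-reproducible per
#' seed.
#'
#' @param n_interactor,n_partner Residues per chain.
#' @param patch Interface patch size (residues per chain in contact range of
#'   the other chain); 0 yields no inter-chain contacts.
#' @param seed Geometry seed.
#' @param aa_interactor,aa_partner Optional one-letter sequences (character
#'   vectors); default poly-alanine.
#' @return A [complex_structure]; the patch positions are attached as
#'   attributes `patch_interactor` / `patch_partner`.
#' @export
generate_complex <- function(n_interactor, n_partner, patch = 3L, seed = 1L,
                             aa_interactor = NULL, aa_partner = NULL) {
  if (patch > min(n_interactor, n_partner)) {
    stopf("interface patch (%d) larger than a chain (%d, %d)", patch, n_interactor, n_partner)
  }
  aa_i <- aa_interactor %||% rep("A", n_interactor)
  aa_p <- aa_partner %||% rep("A", n_partner)
  stopifnot(length(aa_i) == n_interactor, length(aa_p) == n_partner)
  patch_i <- if (patch > 0L) seq.int(floor((n_interactor - patch) / 2) + 1L, length.out = patch) else integer(0)
  patch_p <- if (patch > 0L) seq.int(floor((n_partner - patch) / 2) + 1L, length.out = patch) else integer(0)
  # align patch blocks in x so patch atom m of one chain faces patch atom m of the other
  x0_p <- if (patch > 0L) 3.8 * (patch_i[1L] - patch_p[1L]) else 0
  with_seed(seed, {
    jit <- function(n) lapply(seq_len(n), function(j) matrix(stats::runif(9, -0.05, 0.05), 3L, 3L))
    interactor <- synth_chain("A", aa_i, 0, 0, -1.5, 3.0, patch_i, jit(n_interactor))
    partner <- synth_chain("B", aa_p, x0_p, 10.3, 11.8, 7.3, patch_p, jit(n_partner))
    cx <- complex_structure(interactor, partner, source_tag = sprintf("synthetic seed=%d", seed))
    attr(cx, "patch_interactor") <- patch_i
    attr(cx, "patch_partner") <- patch_p
    cx
  })
}

# single synthetic monomer chain (same layout, no interface plane)
generate_monomer <- function(n_residues, seed = 1L, aa = NULL) {
  aa <- aa %||% rep("A", n_residues)
  with_seed(seed, {
    jit <- lapply(seq_len(n_residues), function(j) matrix(stats::runif(9, -0.05, 0.05), 3L, 3L))
    synth_chain("A", aa, 0, 0, -1.5, 3.0, integer(0), jit)
  })
}

sample_sequence <- function(n, special_pos, special_alphabet, other_alphabet) {
  aa <- sample(other_alphabet, n, replace = TRUE)
  if (length(special_pos)) aa[special_pos] <- sample(special_alphabet, length(special_pos), replace = TRUE)
  aa
}

# clone a sequence with at most `rate` within-class point substitutions so the
# planted composition (and hence the signal) survives in every family member
mutate_within_class <- function(aa, special_pos, rate = 0.1) {
  n <- length(aa)
  k <- sample.int(max(1L, floor(rate * n)), 1L)
  pos <- sample.int(n, k)
  for (p in pos) {
    pool <- if (p %in% special_pos) AA_HYDRO else AA_POLAR
    pool <- setdiff(pool, aa[p])
    aa[p] <- sample(pool, 1L)
  }
  aa
}

central_patch <- function(chain_len, patch) {
  if (patch == 0L) return(integer(0))
  seq.int(floor((chain_len - patch) / 2) + 1L, length.out = patch)
}

away_positions <- function(chain_len, patch) {
  pp <- central_patch(chain_len, patch)
  setdiff(seq_len(chain_len),
          seq.int(max(1L, pp[1L] - 4L), min(chain_len, pp[patch] + 4L)))
}

#' Generate a labeled synthetic PPI perturbation dataset
#'
#' Builds pools of interactor and partner proteins organized in sequence
#' families (each family member is a clone of the family base with at most
#' 10% within-class substitutions), pairs them, generates a synthetic complex
#' per pair, and samples variants half at the interface patch and half far
#' from it (chain distance >= 5 residues). The planted interface-disrupts
#' rule operates at the site level: per (protein, position) the rule is
#' inverted with probability `eps`, so variants at the same site behave
#' consistently across partners (as real site effects do) while a fraction of
#' sites contradicts the interface rule.
#'
#' With `pairing = "random"` proteins recur across pairs and chain lengths
#' vary by family, so concatenated-sequence clustering does not subsume
#' protein sharing and all three paired-input test classes arise in group
#' cross-validation. With `pairing = "diagonal"` each protein appears in
#' exactly one pair and lengths are fixed, so clusters coincide with
#' families.
#'
#' @param n_pairs Number of protein pairs.
#' @param variants_per_pair Variants sampled per pair.
#' @param eps Site-level rule-inversion rate in `[0, 0.5)`.
#' @param seed Master seed.
#' @param patch Interface patch size per chain.
#' @param n_families Number of base families per protein role.
#' @param pairing `"random"` (shared protein pools) or `"diagonal"` (one
#'   pair per protein).
#' @param len_range Candidate chain lengths (one drawn per family and role).
#' @return List with `triplets` (data frame: interactor_id, partner_id,
#'   variant columns, label, source, at_interface), `sequences` (named
#'   character vector), `structures` (named list of [complex_structure] keyed
#'   `"I::P"`), `family` (per-pair interactor family) and `site_flips`
#'   (per-protein positions where the rule is inverted).
#' @export
generate_ppi_dataset <- function(n_pairs = 40L, variants_per_pair = 10L, eps = 0.05,
                                 seed = 1L, patch = 3L, n_families = 3L,
                                 pairing = c("random", "diagonal"),
                                 len_range = 15:21) {
  if (eps < 0 || eps >= 0.5) stopf("label-noise rate must lie in [0, 0.5)")
  pairing <- match.arg(pairing)
  with_seed(seed, {
    if (pairing == "diagonal") {
      n_i <- n_pairs; n_p <- n_pairs
      len_i_fam <- rep(len_range[1L], n_families)
      len_p_fam <- rep(len_range[1L], n_families)
    } else {
      n_i <- max(4L, ceiling(n_pairs / 3))
      n_p <- max(4L, ceiling(n_pairs / 3))
      len_i_fam <- sample(len_range, n_families, replace = TRUE)
      len_p_fam <- sample(len_range, n_families, replace = TRUE)
    }
    fam_of_i <- rep_len(seq_len(n_families), n_i)
    fam_of_p <- rep_len(seq_len(n_families), n_p)
    base_i <- lapply(seq_len(n_families), function(f)
      sample_sequence(len_i_fam[f], central_patch(len_i_fam[f], patch), AA_HYDRO, AA_POLAR))
    base_p <- lapply(seq_len(n_families), function(f)
      sample_sequence(len_p_fam[f], central_patch(len_p_fam[f], patch), AA_HYDRO, AA_POLAR))
    seq_i <- lapply(seq_len(n_i), function(k)
      mutate_within_class(base_i[[fam_of_i[k]]], central_patch(len_i_fam[fam_of_i[k]], patch)))
    seq_p <- lapply(seq_len(n_p), function(k)
      mutate_within_class(base_p[[fam_of_p[k]]], central_patch(len_p_fam[fam_of_p[k]], patch)))
    iids <- sprintf("I%03d", seq_len(n_i))
    pids <- sprintf("P%03d", seq_len(n_p))
    sequences <- c(stats::setNames(vapply(seq_i, paste, character(1), collapse = ""), iids),
                   stats::setNames(vapply(seq_p, paste, character(1), collapse = ""), pids))
    # site-level rule inversions, consistent across partners of a protein
    site_flips <- lapply(seq_len(n_i), function(k)
      which(stats::runif(length(seq_i[[k]])) < eps))
    names(site_flips) <- iids

    if (pairing == "diagonal") {
      combos <- cbind(seq_len(n_pairs), seq_len(n_pairs))
    } else {
      all_combos <- as.matrix(expand.grid(i = seq_len(n_i), p = seq_len(n_p)))
      if (nrow(all_combos) < n_pairs) stopf("protein pools too small for %d pairs", n_pairs)
      combos <- all_combos[sample.int(nrow(all_combos), n_pairs), , drop = FALSE]
    }
    structures <- list()
    rows <- list()
    for (pr in seq_len(n_pairs)) {
      ki <- combos[pr, 1L]; kp <- combos[pr, 2L]
      iid <- iids[ki]; pid <- pids[kp]
      aa_i <- seq_i[[ki]]; aa_p <- seq_p[[kp]]
      structures[[pair_id(iid, pid)]] <- generate_complex(
        length(aa_i), length(aa_p), patch, seed = sample.int(2147483646L, 1L),
        aa_interactor = aa_i, aa_partner = aa_p)
      patch_pos <- central_patch(length(aa_i), patch)
      away_pos <- away_positions(length(aa_i), patch)
      n_if <- ceiling(variants_per_pair / 2)
      at_interface <- c(rep(TRUE, n_if), rep(FALSE, variants_per_pair - n_if))
      for (v in seq_len(variants_per_pair)) {
        pos <- if (at_interface[v]) sample(patch_pos, 1L) else sample(away_pos, 1L)
        wt <- aa_i[pos]
        mut <- sample(setdiff(AA_ALL, wt), 1L)
        disruptive <- xor(at_interface[v], pos %in% site_flips[[iid]])
        rows[[length(rows) + 1L]] <- data.frame(
          interactor_id = iid, partner_id = pid,
          wt_aa = wt, position = pos, mut_aa = mut,
          label = if (disruptive) "disruptive" else "non-disruptive",
          source = "synthetic", at_interface = at_interface[v],
          stringsAsFactors = FALSE)
      }
    }
    triplets <- do.call(rbind, rows)
    triplets$variant <- sprintf("p.%s%d%s", triplets$wt_aa, triplets$position, triplets$mut_aa)
    list(triplets = triplets, sequences = sequences, structures = structures,
         family = fam_of_i[combos[, 1L]], site_flips = site_flips)
  })
}

#' Generate a labeled synthetic stability dataset
#'
#' Monomeric chains with a buried hydrophobic core (central block drawn from
#' the hydrophobic alphabet). Variants are sampled half at the core and half
#' away; ddG magnitudes are drawn so core variants are stability-disrupting
#' (|ddG| >= 1.5 kcal/mol) and surface variants stability-preserving
#' (|ddG| < 0.5), with the category flipped with probability `eps`.
#'
#' @param n_proteins Number of monomer proteins.
#' @param variants_per_protein Variants sampled per protein.
#' @param eps Category-noise rate in `[0, 0.5)`.
#' @param seed Master seed.
#' @param chain_len Residues per chain.
#' @param core Core block size.
#' @return List with `records` (protein_id, variant columns, ddG, buried),
#'   `sequences` and `structures` (named list of [chain_structure]).
#' @export
generate_stability_dataset <- function(n_proteins = 20L, variants_per_protein = 12L,
                                       eps = 0.05, seed = 1L, chain_len = 15L, core = 3L) {
  if (eps < 0 || eps >= 0.5) stopf("label-noise rate must lie in [0, 0.5)")
  core_start <- floor((chain_len - core) / 2) + 1L
  core_pos <- seq.int(core_start, length.out = core)
  away_pos <- setdiff(seq_len(chain_len), core_pos)
  with_seed(seed, {
    sequences <- character(0)
    structures <- list()
    rows <- list()
    for (pr in seq_len(n_proteins)) {
      aa <- sample_sequence(chain_len, core_pos, AA_HYDRO, AA_POLAR)
      id <- sprintf("S%03d", pr)
      sequences[[id]] <- paste(aa, collapse = "")
      structures[[id]] <- generate_monomer(chain_len, seed = sample.int(2147483646L, 1L), aa = aa)
      n_core <- ceiling(variants_per_protein / 2)
      buried <- c(rep(TRUE, n_core), rep(FALSE, variants_per_protein - n_core))
      for (v in seq_len(variants_per_protein)) {
        pos <- if (buried[v]) sample(core_pos, 1L) else sample(away_pos, 1L)
        wt <- aa[pos]
        mut <- sample(setdiff(AA_ALL, wt), 1L)
        disrupt <- xor(buried[v], stats::runif(1) < eps)
        mag <- if (disrupt) stats::runif(1, 1.5, 4.5) else stats::runif(1, 0, 0.49)
        ddg <- mag * sample(c(-1, 1), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = id, wt_aa = wt, position = pos, mut_aa = mut,
          ddG = ddg, buried = buried[v], stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    records$variant <- sprintf("p.%s%d%s", records$wt_aa, records$position, records$mut_aa)
    records$label <- label_stability(records$ddG)
    list(records = records, sequences = sequences, structures = structures)
  })
}

#' Generate a planted edgotype scenario
#'
#' For each stratum, draws each variant's edgotype from the planted
#' (quasi-null, edgetic, quasi-wild-type) rates and then partner-wise loss
#' probabilities consistent with it: all below 0.5, all at or above 0.5, or
#' mixed. Observed stratum rates converge to the planted rates as the number
#' of variants grows, and [classify_edgotype()] reproduces the drawn edgotype
#' for every generated profile.
#'
#' @param strata Named list; each element a list with `qn` and `edgetic`
#'   rates (quasi-wild-type is the remainder, which must be non-negative),
#'   `n` variants, and optionally `partners` (vector of partner counts to
#'   sample from; default 3:8).
#' @param seed Master seed.
#' @return Named list (per stratum) of lists of [variant_profile]s.
#' @export
generate_edgotype_scenario <- function(strata, seed = 1L) {
  for (nm in names(strata)) {
    st <- strata[[nm]]
    if (st$qn < 0 || st$edgetic < 0 || st$qn + st$edgetic > 1 + 1e-12) {
      stopf("stratum '%s': rates must be in [0,1] and sum to at most 1", nm)
    }
  }
  with_seed(seed, {
    lapply(stats::setNames(names(strata), names(strata)), function(nm) {
      st <- strata[[nm]]
      partners <- st$partners %||% 3:8
      lapply(seq_len(st$n), function(v) {
        edgo <- sample(c("quasi-null", "edgetic", "quasi-wild-type"), 1L,
                       prob = c(st$qn, st$edgetic, 1 - st$qn - st$edgetic))
        k <- if (length(partners) == 1L) partners else sample(partners, 1L)
        if (edgo == "edgetic") k <- max(k, 2L)
        probs <- switch(edgo,
          "quasi-wild-type" = stats::runif(k, 0.02, 0.47),
          "quasi-null" = stats::runif(k, 0.53, 0.98),
          "edgetic" = {
            n_hi <- sample.int(k - 1L, 1L)
            sample(c(stats::runif(n_hi, 0.53, 0.98), stats::runif(k - n_hi, 0.02, 0.47)))
          })
        variant_profile(sprintf("%s_V%04d", nm, v), sprintf("A%dV", v),
                        sprintf("Q%03d", seq_len(k)), probs)
      })
    })
  })
}
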