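#' Variant profile: partner-wise interaction-loss probabilities
#'
#' @param interactor_id Protein id carrying the variant.
#' @param variant Variant string (e.g. `"C61G"`).
#' @param partner_ids Character vector of partner protein ids.
#' @param probs Numeric vector of predicted loss probabilities in (0, 1), one
#'   per partner.
#' @param available_partners Number of partners available in the interaction
#'   catalogue (e.g. BioGRID); defaults to the number tested.
#' @return An object of class `variant_profile`.
#' @export
variant_profile <- function(interactor_id, variant, partner_ids, probs,
                            available_partners = length(probs)) {
  if (length(probs) < 1L) stopf("a variant profile needs at least one partner prediction")
  if (length(partner_ids) != length(probs)) stopf("partner ids and probabilities differ in length")
  if (any(probs <= 0 | probs >= 1)) stopf("loss probabilities must lie strictly in (0, 1)")
  structure(list(interactor_id = interactor_id, variant = variant,
                 partner_ids = partner_ids, probs = probs,
                 tested_partners = length(probs),
                 available_partners = as.integer(available_partners)),
            class = "variant_profile")
}

#' Classify a variant's edgotype
#'
#' All partner probabilities below the threshold: quasi-wild-type; all at or
#' above it: quasi-null; mixed: edgetic. A probability exactly equal to the
#' threshold counts as perturbed.
#'
#' @param profile A [variant_profile], or a bare numeric vector of
#'   probabilities.
#' @param threshold Perturbation threshold; default 0.5.
#' @return One of `"quasi-wild-type"`, `"edgetic"`, `"quasi-null"`.
#' @export
classify_edgotype <- function(profile, threshold = 0.5) {
  probs <- if (inherits(profile, "variant_profile")) profile$probs else profile
  if (length(probs) < 1L) stopf("cannot classify an empty profile")
  perturbed <- probs >= threshold
  if (all(perturbed)) "quasi-null"
  else if (!any(perturbed)) "quasi-wild-type"
  else "edgetic"
}

#' Partner-coverage filter
#'
#' Drops variants with fewer than three tested partners when the catalogue
#' holds three or more partners; variants whose catalogue itself has fewer
#' than three partners are processed normally.
#'
#' @param profiles List of [variant_profile]s.
#' @return List with `kept` (profiles passing the filter) and `report`
#'   (`kept`, `dropped` counts).
#' @export
filter_partner_coverage <- function(profiles) {
  drop <- vapply(profiles, function(p) {
    p$available_partners >= 3L && p$tested_partners < 3L
  }, logical(1))
  list(kept = profiles[!drop],
       report = c(kept = sum(!drop), dropped = sum(drop)))
}

#' Enrichment trend statistic
#'
#' `E = (f_obs - f_gnomad) / (f_obs + f_gnomad)`, a signed measure in
#' `[-1, 1]` of over/under-representation of an edgotype in a variant group
#' relative to the population baseline: positive iff `f_obs > f_gnomad`, with
#' the extremes attained exactly when one rate is zero. Undefined when both
#' rates are zero (an error, never reported as 0).
#'
#' @param f_obs,f_gnomad Observed rates in `[0, 1]`.
#' @return E in `[-1, 1]`.
#' @export
enrichment_trend <- function(f_obs, f_gnomad) {
  if (any(f_obs < 0 | f_obs > 1) || any(f_gnomad < 0 | f_gnomad > 1)) {
    stopf("rates must lie in [0, 1]")
  }
  if (any(f_obs + f_gnomad == 0)) {
    stopf("enrichment undefined: both rates are zero")
  }
  (f_obs - f_gnomad) / (f_obs + f_gnomad)
}

# Probability that a variant shows `effect` when `size` partners are sampled
# without replacement (hypergeometric over the count of perturbed partners);
# with size == k this degenerates to the observed edgotype indicator.
effect_prob_subsample <- function(profile, effect, size, threshold) {
  k <- profile$tested_partners
  s <- min(size, k)
  m <- sum(profile$probs >= threshold)
  p_qn <- if (m >= s) choose(m, s) / choose(k, s) else 0
  p_qwt <- if (k - m >= s) choose(k - m, s) / choose(k, s) else 0
  switch(effect,
         "quasi-null" = p_qn,
         "quasi-wild-type" = p_qwt,
         "edgetic" = 1 - p_qn - p_qwt)
}

#' Bootstrap test of edgotype enrichment
#'
#' Point estimate: E computed from the full-data effect rates of the group
#' and the baseline. Each bootstrap iteration resamples variants (profiles,
#' not partner pairs) with replacement independently within group and
#' baseline; in partner-controlled mode exactly `partner_sample_size`
#' partners are sampled uniformly without replacement per resampled variant
#' (variants with fewer tested partners use all of them), edgotypes are
#' re-classified and E recomputed. Iterations where both rates are zero are
#' discarded and counted. Significance is sign consistency: the fraction of
#' defined iterations whose E has the sign of the point estimate, compared to
#' `1 - alpha/n_tests` (Bonferroni) and `1 - alpha` (uncorrected). The 68%
#' confidence interval is the (16th, 84th) percentile pair of the bootstrap E
#' distribution.
#'
#' @param group,baseline Non-empty lists of [variant_profile]s.
#' @param effect `"quasi-null"` or `"edgetic"` (or `"quasi-wild-type"`).
#' @param B Bootstrap iterations; default 100000.
#' @param alpha Significance level; default 0.05.
#' @param n_tests Bonferroni correction denominator; default 64.
#' @param partner_control Sample exactly `partner_sample_size` partners per
#'   variant per iteration (applied to group and baseline alike).
#' @param partner_sample_size Partners per variant in partner-controlled mode;
#'   default 3.
#' @param threshold Perturbation threshold; default 0.5.
#' @param seed Integer seed; identical seeds give identical results.
#' @return Object of class `enrichment_result`: list with `effect`, `E`,
#'   `ci` (68% bounds), `consistency`, `significant_bonferroni`,
#'   `significant_uncorrected`, `n_group`, `n_baseline`, `undefined_iterations`
#'   and the full-data rates. When both full-data rates are zero the point
#'   estimate is reported as not computable (`E = NA`).
#' @export
bootstrap_enrichment <- function(group, baseline, effect = c("quasi-null", "edgetic", "quasi-wild-type"),
                                 B = 100000L, alpha = 0.05, n_tests = 64L,
                                 partner_control = FALSE, partner_sample_size = 3L,
                                 threshold = 0.5, seed = 1L) {
  effect <- match.arg(effect)
  if (length(group) == 0L || length(baseline) == 0L) {
    stopf("group and baseline must be non-empty")
  }
  g_obs <- vapply(group, function(p) classify_edgotype(p, threshold) == effect, logical(1))
  b_obs <- vapply(baseline, function(p) classify_edgotype(p, threshold) == effect, logical(1))
  f_obs <- mean(g_obs)
  f_base <- mean(b_obs)
  point <- if (f_obs + f_base == 0) NA_real_ else (f_obs - f_base) / (f_obs + f_base)

  sz <- if (partner_control) partner_sample_size else Inf
  g_p <- vapply(group, effect_prob_subsample, numeric(1), effect, sz, threshold)
  b_p <- vapply(baseline, effect_prob_subsample, numeric(1), effect, sz, threshold)

  ng <- length(g_p); nb <- length(b_p)
  E_b <- with_seed(seed, {
    out <- numeric(B)
    chunk <- max(1L, min(B, as.integer(2e6 / (ng + nb))))
    done <- 0L
    while (done < B) {
      m <- min(chunk, B - done)
      gp <- matrix(g_p[sample.int(ng, ng * m, replace = TRUE)], ng, m)
      bp <- matrix(b_p[sample.int(nb, nb * m, replace = TRUE)], nb, m)
      fg <- colMeans(matrix(stats::runif(ng * m) < gp, ng, m))
      fb <- colMeans(matrix(stats::runif(nb * m) < bp, nb, m))
      tot <- fg + fb
      out[done + seq_len(m)] <- ifelse(tot == 0, NA_real_, (fg - fb) / tot)
      done <- done + m
    }
    out
  })
  undefined <- sum(is.na(E_b))
  E_def <- E_b[!is.na(E_b)]
  if (length(E_def) == 0L) {
    return(structure(list(effect = effect, E = point, ci = c(NA_real_, NA_real_),
                          consistency = NA_real_, significant_bonferroni = FALSE,
                          significant_uncorrected = FALSE, n_group = ng, n_baseline = nb,
                          f_obs = f_obs, f_baseline = f_base, B = B,
                          undefined_iterations = undefined, computable = FALSE),
                     class = "enrichment_result"))
  }
  consistency <- if (is.na(point)) NA_real_ else mean(sign(E_def) == sign(point))
  ci <- unname(stats::quantile(E_def, c(0.16, 0.84)))
  structure(list(effect = effect, E = point, ci = ci,
                 consistency = consistency,
                 significant_bonferroni = isTRUE(consistency >= 1 - alpha / n_tests),
                 significant_uncorrected = isTRUE(consistency >= 1 - alpha),
                 n_group = ng, n_baseline = nb,
                 f_obs = f_obs, f_baseline = f_base, B = B,
                 undefined_iterations = undefined, computable = TRUE),
            class = "enrichment_result")
}

#' Enrichment report over variant strata
#'
#' Computes one [bootstrap_enrichment()] result per (stratum, effect) pair
#' against a designated baseline stratum, sorted by stratum name.
#'
#' @param strata Named list of profile lists (one element per stratum,
#'   including the baseline).
#' @param baseline Name of the baseline stratum (e.g. the population panel).
#' @param effects Effects to test; default quasi-null and edgetic.
#' @param n_tests Bonferroni denominator; defaults to
#'   `2 * (number of non-baseline strata)`.
#' @inheritParams bootstrap_enrichment
#' @return Data frame with one row per (stratum, effect): `stratum`, `effect`,
#'   `E`, `ci_low`, `ci_high`, `consistency`, `significant_bonferroni`,
#'   `significant_uncorrected`, `n`.
#' @export
repository_report <- function(strata, baseline, effects = c("quasi-null", "edgetic"),
                              B = 100000L, alpha = 0.05, n_tests = NULL,
                              partner_control = FALSE, partner_sample_size = 3L,
                              threshold = 0.5, seed = 1L) {
  if (!baseline %in% names(strata)) stopf("baseline stratum '%s' not found", baseline)
  groups <- sort(setdiff(names(strata), baseline))
  n_tests <- n_tests %||% (length(effects) * length(groups))
  seeds <- derive_seeds(seed, length(groups) * length(effects))
  rows <- list()
  si <- 0L
  for (g in groups) {
    for (eff in effects) {
      si <- si + 1L
      res <- bootstrap_enrichment(strata[[g]], strata[[baseline]], eff,
                                  B = B, alpha = alpha, n_tests = n_tests,
                                  partner_control = partner_control,
                                  partner_sample_size = partner_sample_size,
                                  threshold = threshold, seed = seeds[si])
      rows[[si]] <- data.frame(stratum = g, effect = eff, E = res$E,
                               ci_low = res$ci[1L], ci_high = res$ci[2L],
                               consistency = res$consistency,
                               significant_bonferroni = res$significant_bonferroni,
                               significant_uncorrected = res$significant_uncorrected,
                               n = res$n_group)
    }
  }
  do.call(rbind, rows)
}
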