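test_that("edgotype classification follows the all/none/mixed rule at threshold 0.5", {
  expect_equal(classify_edgotype(c(0.1, 0.2, 0.3)), "quasi-wild-type")
  expect_equal(classify_edgotype(c(0.9, 0.6, 0.51)), "quasi-null")
  expect_equal(classify_edgotype(c(0.9, 0.1)), "edgetic")
  expect_equal(classify_edgotype(0.7), "quasi-null")
  # a probability exactly at the threshold counts as perturbed
  expect_equal(classify_edgotype(c(0.5, 0.6)), "quasi-null")
  expect_equal(classify_edgotype(c(0.5, 0.4)), "edgetic")
  expect_error(classify_edgotype(numeric(0)), "empty")
})

test_that("edgotypes are exhaustive over any profile set", {
  sc <- generate_edgotype_scenario(list(s = list(qn = 0.3, edgetic = 0.3, n = 150)), seed = 2)
  types <- vapply(sc$s, classify_edgotype, character(1))
  expect_equal(sum(table(factor(types, c("quasi-wild-type", "edgetic", "quasi-null")))), 150)
})

test_that("partner-coverage filter drops only under-tested variants with rich catalogues", {
  mk <- function(tested, avail) variant_profile("I1", "A1V", sprintf("P%d", seq_len(tested)),
                                                rep(0.3, tested), available_partners = avail)
  out <- filter_partner_coverage(list(mk(2, 10), mk(2, 2), mk(3, 3)))
  expect_equal(unname(out$report), c(2L, 1L))
  expect_equal(vapply(out$kept, `[[`, integer(1), "available_partners"), c(2L, 3L))
})

test_that("enrichment trend matches its closed form, bounds and antisymmetry", {
  expect_equal(enrichment_trend(0.2, 0.2), 0)
  expect_equal(enrichment_trend(0.5, 0.25), 1 / 3)
  expect_equal(enrichment_trend(0.4, 0), 1)
  expect_equal(enrichment_trend(0, 0.4), -1)
  expect_error(enrichment_trend(0, 0), "both rates are zero")
  expect_error(enrichment_trend(1.2, 0.1), "\\[0, 1\\]")
  set.seed(4)
  a <- runif(200); b <- runif(200)
  E <- enrichment_trend(a, b)
  expect_true(all(E >= -1 & E <= 1))
  expect_equal(enrichment_trend(b, a), -E)
  expect_equal(abs(E) == 1, (a == 0) | (b == 0))
  # strictly increasing in f_obs for fixed baseline
  f <- seq(0, 1, by = 0.01)
  expect_true(all(diff(enrichment_trend(f, 0.3)) > 0))
})

test_that("bootstrap enrichment recovers a planted effect and rejects the null", {
  sc <- generate_edgotype_scenario(
    list(group = list(qn = 0.6, edgetic = 0.2, n = 200),
         base = list(qn = 0.1, edgetic = 0.2, n = 200)), seed = 14)
  res <- bootstrap_enrichment(sc$group, sc$base, "quasi-null", B = 4000, seed = 3)
  planted <- (0.6 - 0.1) / (0.6 + 0.1)
  expect_gt(res$E, 0.5)
  expect_true(res$ci[1] <= planted && planted <= res$ci[2])
  expect_true(res$significant_bonferroni)
  expect_true(res$significant_uncorrected)
  expect_identical(res,
                   bootstrap_enrichment(sc$group, sc$base, "quasi-null", B = 4000, seed = 3))

  null_res <- bootstrap_enrichment(sc$base, sc$base, "quasi-null", B = 2000, seed = 5)
  expect_equal(null_res$E, 0)
  expect_false(null_res$significant_bonferroni)
  expect_false(null_res$significant_uncorrected)
  expect_error(bootstrap_enrichment(list(), sc$base, "quasi-null"), "non-empty")
})

test_that("sign consistency rises from chance toward one with effect size", {
  mk_sc <- function(qn, seed) generate_edgotype_scenario(
    list(g = list(qn = qn, edgetic = 0.2, n = 150),
         b = list(qn = 0.2, edgetic = 0.2, n = 150)), seed = seed)
  weak <- mk_sc(0.22, 31)
  strong <- mk_sc(0.7, 32)
  c_weak <- bootstrap_enrichment(weak$g, weak$b, "quasi-null", B = 1500, seed = 1)$consistency
  c_strong <- bootstrap_enrichment(strong$g, strong$b, "quasi-null", B = 1500, seed = 1)$consistency
  expect_lt(c_weak, 0.95)
  expect_gt(c_strong, 0.99)
})

test_that("partner-controlled bootstrap samples exactly three partners per variant", {
  # a variant with 1 perturbed of 6 partners is rarely quasi-null under
  # 3-partner subsampling: P = C(1,3)/C(6,3) = 0
  p <- variant_profile("I1", "A1V", sprintf("P%d", 1:6), c(0.9, rep(0.1, 5)))
  expect_equal(edgotyper:::effect_prob_subsample(p, "quasi-null", 3, 0.5), 0)
  expect_equal(edgotyper:::effect_prob_subsample(p, "quasi-wild-type", 3, 0.5),
               choose(5, 3) / choose(6, 3))
  expect_equal(edgotyper:::effect_prob_subsample(p, "edgetic", 3, 0.5),
               1 - choose(5, 3) / choose(6, 3))
  # fewer tested partners than the sample size: all of them are used
  p2 <- variant_profile("I1", "A1V", c("P1", "P2"), c(0.9, 0.8))
  expect_equal(edgotyper:::effect_prob_subsample(p2, "quasi-null", 3, 0.5), 1)
})

test_that("repository reports produce one row per stratum and effect", {
  sc <- generate_edgotype_scenario(
    list(high = list(qn = 0.5, edgetic = 0.3, n = 80),
         low = list(qn = 0.15, edgetic = 0.2, n = 80),
         pop = list(qn = 0.1, edgetic = 0.15, n = 120)), seed = 9)
  rep_ <- repository_report(sc, baseline = "pop", B = 800, seed = 2)
  expect_equal(nrow(rep_), 4L)
  expect_setequal(rep_$stratum, c("high", "low"))
  expect_setequal(rep_$effect, c("quasi-null", "edgetic"))
  # planted quasi-null monotone: high stratum enriched above low
  eh <- rep_$E[rep_$stratum == "high" & rep_$effect == "quasi-null"]
  el <- rep_$E[rep_$stratum == "low" & rep_$effect == "quasi-null"]
  expect_gt(eh, el)
  expect_error(repository_report(sc, baseline = "missing"), "not found")
})
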