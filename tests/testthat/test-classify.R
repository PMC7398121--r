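test_that("posterior combination obeys the odds-form identities", {
  expect_equal(combine_posterior(0.5, c(1, 1, 1)), 0.5)
  # odds 1/9 * 81 = 9 -> 9/10, checked by direct arithmetic
  expect_equal(combine_posterior(0.1, 81), 9 / 10, tolerance = 1e-12)
  for (p in c(0.01, 0.3, 0.9))
    for (L in c(0.2, 5, 40))
      expect_equal(combine_posterior(p, c(L, 1 / L)), p, tolerance = 1e-12)
  # permutation invariance and log-odds additivity
  lrs <- c(2.5, 0.3, 7, 1.2)
  expect_equal(combine_posterior(0.2, lrs), combine_posterior(0.2, rev(lrs)),
               tolerance = 1e-15)
  direct <- (0.2 / 0.8 * prod(lrs)) / (1 + 0.2 / 0.8 * prod(lrs))
  expect_equal(combine_posterior(0.2, lrs), direct, tolerance = 1e-12)
  # strictly increasing in each LR
  base <- combine_posterior(0.2, lrs)
  for (i in seq_along(lrs)) {
    up <- lrs; up[i] <- up[i] * 1.5
    expect_gt(combine_posterior(0.2, up), base)
  }
  expect_error(combine_posterior(0, 2), "prior")
  expect_error(combine_posterior(0.5, c(1, -2)), "positive")
})

test_that("posterior-to-class boundaries sit exactly at the published cut-offs", {
  expect_identical(posterior_to_class(0.95), 4L)
  expect_identical(posterior_to_class(0.049), 2L)
  expect_identical(posterior_to_class(0.05), 3L)
  expect_identical(posterior_to_class(0.5), 3L)
  expect_identical(posterior_to_class(0.99), 4L)
  expect_identical(posterior_to_class(0.991), 5L)
  expect_identical(posterior_to_class(0.001), 2L)
  expect_identical(posterior_to_class(0.0009), 1L)
  # monotone step function
  ps <- sort(stats::runif(200))
  expect_true(all(diff(vapply(ps, posterior_to_class, integer(1))) >= 0L))
  expect_error(posterior_to_class(1.2), "\\[0, 1\\]")
})

test_that("functional LR calibration is config-driven with a neutral fallback", {
  expect_identical(functional_lr(10, "MLH1", NULL), 1.0)
  expect_error(functional_lr(10, "MLH1", NULL, strict = TRUE), "calibration")
  step <- list(type = "step", values = c(deficient = 10, moderate = 1, proficient = 0.1))
  expect_identical(functional_lr(10, "MLH1", step), 10)    # 10% -> deficient
  expect_identical(functional_lr(50, "MLH1", step), 1)
  expect_identical(functional_lr(90, "MLH1", step), 0.1)
  lin <- list(type = "linear", percent = c(0, 50, 100), lr = c(20, 1, 0.2))
  lrs <- vapply(seq(0, 110, by = 5), functional_lr, numeric(1),
                gene_symbol = "MSH2", calibration = lin)
  expect_true(all(diff(lrs) <= 0))           # monotone non-increasing
})

test_that("the decision-tree rules reproduce the worked classification cases", {
  # complete impact with a frameshift product and no other evidence:
  # pathogenic, and the splicing evidence is decisive
  e <- evidence_bundle("missense", splicing_impact = "complete",
                       allele_specific = TRUE,
                       aberrant_transcript_frame = "ptc_or_frameshift",
                       nmd_inhibitor_used = TRUE)
  cl <- apply_rules(e)
  expect_identical(cl$insight_class, 5L)
  expect_true("complete_ptc_null_allele" %in% cl$rationale)
  expect_true(splicing_contribution(e))

  # silent variant, no aberration, NMD inhibited: likely benign via splicing
  e <- evidence_bundle("silent", splicing_impact = "none",
                       nmd_inhibitor_used = TRUE)
  expect_identical(apply_rules(e)$insight_class, 2L)
  expect_true(splicing_contribution(e))
  # ... but without NMD inhibition the variant stays VUS
  e_no <- evidence_bundle("silent", splicing_impact = "none",
                          nmd_inhibitor_used = FALSE)
  cl <- apply_rules(e_no)
  expect_identical(cl$insight_class, 3L)
  expect_true("nmd_uninhibited_vus_cap" %in% cl$rationale)

  # incomplete impact alone contributes nothing
  e <- evidence_bundle("missense", splicing_impact = "incomplete",
                       allele_specific = TRUE,
                       aberrant_transcript_frame = "ptc_or_frameshift",
                       nmd_inhibitor_used = TRUE)
  cl <- apply_rules(e)
  expect_identical(cl$insight_class, 3L)
  expect_false(splicing_contribution(e))

  # canonical donor with unknown impact: assay alone gives likely
  # pathogenic; concordant quantitative evidence lifts it to pathogenic
  # without the splicing assay being decisive
  e <- evidence_bundle("splice_site", splicing_impact = "unknown",
                       aberrant_transcript_frame = "ptc_or_frameshift",
                       nmd_inhibitor_used = TRUE)
  expect_identical(apply_rules(e)$insight_class, 4L)
  e_q <- evidence_bundle("splice_site", splicing_impact = "unknown",
                         likelihood_ratios = c(tumor = 30, segregation = 40),
                         aberrant_transcript_frame = "ptc_or_frameshift",
                         nmd_inhibitor_used = TRUE)
  expect_identical(apply_rules(e_q)$insight_class, 5L)
  expect_false(splicing_contribution(e_q))

  # predicted loss-of-function types are pathogenic regardless of splicing
  e <- evidence_bundle("nonsense", splicing_impact = "incomplete",
                       nmd_inhibitor_used = TRUE)
  expect_identical(apply_rules(e)$insight_class, 5L)
})

test_that("splicing contribution is the class difference with and without the assay", {
  # class already pathogenic from clinical/functional evidence, splicing normal
  e <- evidence_bundle("missense", likelihood_ratios = c(8, 15, 10),
                       splicing_impact = "none", nmd_inhibitor_used = TRUE,
                       function_category = "deficient")
  expect_identical(apply_rules(e)$insight_class, 5L)
  expect_false(splicing_contribution(e))
  # empty evidence: VUS either way
  e <- evidence_bundle("missense")
  expect_identical(apply_rules(e)$insight_class, 3L)
  expect_false(splicing_contribution(e))
})

test_that("qualitative and quantitative routes reconcile toward the stronger same-side class, conflict to VUS", {
  # same side, pathogenic: 5 over 4
  e <- evidence_bundle("splice_site", likelihood_ratios = c(30, 40),
                       splicing_impact = "unknown", nmd_inhibitor_used = TRUE)
  cl <- apply_rules(e)
  expect_identical(cl$qualitative_class, 4L)
  expect_identical(cl$quantitative_class, 5L)
  expect_identical(cl$insight_class, 5L)
  expect_false(cl$conflict)
  # same side, benign: 1 over 2
  e <- evidence_bundle("silent", likelihood_ratios = c(0.05, 0.1),
                       splicing_impact = "none", nmd_inhibitor_used = TRUE)
  cl <- apply_rules(e)
  expect_identical(cl$qualitative_class, 2L)
  expect_identical(cl$quantitative_class, 1L)
  expect_identical(cl$insight_class, 1L)
  # opposite sides: VUS with conflict flag
  e <- evidence_bundle("splice_site", likelihood_ratios = c(0.01, 0.05),
                       splicing_impact = "unknown", nmd_inhibitor_used = TRUE)
  cl <- apply_rules(e)
  expect_identical(cl$insight_class, 3L)
  expect_true(cl$conflict)
  expect_true("qualitative_quantitative_conflict" %in% cl$rationale)
})

test_that("removing splicing evidence never flips a class across the VUS band", {
  set.seed(77)
  types <- c("missense", "silent", "intronic", "splice_site")
  impacts <- c("complete", "incomplete", "unknown", "none", NA)
  lr_sets <- list(numeric(), c(30, 40), c(0.05, 0.1), 300)
  for (i in 1:200) {
    imp <- sample(impacts, 1)
    e <- evidence_bundle(sample(types, 1),
                         likelihood_ratios = lr_sets[[sample(4, 1)]],
                         splicing_impact = imp,
                         nmd_inhibitor_used = if (is.na(imp)) NA else TRUE,
                         allele_specific = sample(c(TRUE, FALSE), 1),
                         aberrant_transcript_frame =
                           if (!is.na(imp) && imp != "none")
                             sample(c("ptc_or_frameshift", "in_frame"), 1)
                           else NA_character_)
    with_s <- apply_rules(e)$insight_class
    without_s <- apply_rules(mmrsplice:::strip_splicing(e))$insight_class
    expect_false(with_s >= 4L && without_s <= 2L)
    expect_false(with_s <= 2L && without_s >= 4L)
  }
})

test_that("contradictory bundles are rejected", {
  e <- evidence_bundle("missense", splicing_impact = "none",
                       aberrant_transcript_frame = "ptc_or_frameshift")
  expect_error(apply_rules(e), "contradictory")
  expect_error(evidence_bundle("weird_type"), "variant_type")
  expect_error(evidence_bundle("missense", prior_prob = 1.5), "prior")
  expect_error(evidence_bundle("missense", splicing_impact = "partial"),
               "splicing_impact")
})
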