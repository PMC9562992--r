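# The evidence-combination engine: published example profiles, conflict
# handling, ablation, and agreement with the independent rule oracle.

test_that("published evidence profiles combine to their published tiers", {
  lp1 <- combine_evidence(table4_profile("c.316C>T"))
  expect_equal(lp1$tier, "likely_pathogenic")     # 2 moderate + 2 supporting
  expect_equal(lp1$rationale, "no_conflict")
  expect_equal(lp1$matched_rule, "LP:2M+2P")

  vus_ins <- combine_evidence(table4_profile("c.2450A>G"))
  expect_equal(vus_ins$tier, "uncertain_significance")  # 1 moderate + 3 supporting
  expect_equal(vus_ins$rationale, "insufficient_evidence")
  expect_true(is.na(vus_ins$matched_rule))

  conflict <- combine_evidence(table4_profile("c.664G>A"))
  expect_equal(conflict$tier, "uncertain_significance")
  expect_equal(conflict$rationale, "evidence_in_conflict")
  expect_match(conflict$matched_rule, "LB:BS\\+BP")

  lp7 <- combine_evidence(table4_profile("c.1123C>T"))
  expect_equal(lp7$tier, "likely_pathogenic")
  expect_equal(lp7$matched_rule, "LP:3M")

  expect_equal(combine_evidence(table4_profile("c.1378G>A"))$tier,
               "uncertain_significance")

  empty <- combine_evidence(evidence_profile())
  expect_equal(empty$tier, "uncertain_significance")
  expect_equal(empty$rationale, "insufficient_evidence")
})

test_that("modified strengths count in their applied slot, not the base slot", {
  # PS3 applied as supporting: supporting count, not strong
  cnt <- strength_counts(table4_profile("c.316C>T"))
  expect_equal(unname(cnt[c("vs", "s", "m", "p")]), c(0L, 0L, 2L, 2L))
  # PS3 at its base strength would make the same profile likely pathogenic
  # via the strong+moderate route instead
  strong_ps3 <- evidence_profile(
    evidence_item("PS3", "strong"),
    evidence_item("PM2", "moderate", "supporting"),
    evidence_item("PM3", "moderate"),
    evidence_item("PP4", "supporting", "moderate")
  )
  res <- combine_evidence(strong_ps3)
  expect_equal(res$tier, "likely_pathogenic")
  expect_equal(res$matched_rule, "LP:S+1-2M")
})

test_that("benign items map onto the stand-alone/strong/supporting slots", {
  p <- evidence_profile(
    evidence_item("BS1", "strong"),
    evidence_item("BS3", "strong", "very_strong"),  # counts as strong
    evidence_item("BP4", "supporting"),
    evidence_item("BP7", "supporting", "moderate")  # counts as supporting
  )
  cnt <- strength_counts(p)
  expect_equal(unname(cnt[c("sa", "bs", "bp")]), c(0L, 2L, 2L))
  expect_equal(combine_evidence(p)$tier, "benign")
  expect_equal(combine_evidence(evidence_profile(
    evidence_item("BA1", "stand_alone")))$tier, "benign")
})

test_that("duplicate codes are rejected; pass-through codes are accepted", {
  expect_error(evidence_profile(evidence_item("PM2", "moderate"),
                                evidence_item("PM2", "moderate")),
               "duplicate")
  # codes not assigned by this pipeline still combine (category by prefix)
  res <- combine_evidence(evidence_profile(
    evidence_item("PVS1", "very_strong"),
    evidence_item("PS1", "strong")
  ))
  expect_equal(res$tier, "pathogenic")
})

test_that("ablating PS3 reports each variant's dependence on the assay", {
  # without functional data the first variant reverts to VUS
  expect_equal(ablate(table4_profile("c.316C>T"), "PS3")$tier,
               "uncertain_significance")
  # this one still reaches likely pathogenic on clinical + public data
  expect_equal(ablate(table4_profile("c.1721T>C"), "PS3")$tier,
               "likely_pathogenic")
  # removing an absent code is a no-op
  p <- table4_profile("c.1123C>T")
  expect_equal(ablate(p, "PS3")$tier, combine_evidence(p)$tier)
  expect_equal(ablate(p, "PS3")$matched_rule,
               combine_evidence(p)$matched_rule)
})

test_that("the engine agrees with the rule oracle on sampled count vectors", {
  set.seed(2024)
  idx <- expand.grid(vs = 0:4, s = 0:4, m = 0:4, p = 0:4,
                     sa = 0:4, bs = 0:4, bp = 0:4)
  take <- idx[sample(nrow(idx), 3000), ]
  expect_oracle <- oracle_combine(take$vs, take$s, take$m, take$p,
                                  take$sa, take$bs, take$bp)
  for (k in seq_len(nrow(take))) {
    g <- take[k, ]
    res <- combine_evidence(profile_from_counts(g$vs, g$s, g$m, g$p,
                                                g$sa, g$bs, g$bp))
    expect_identical(res$tier, expect_oracle$tier[k])
    expect_identical(res$rationale, expect_oracle$rationale[k])
  }
})

test_that("adding same-category evidence never moves the tier the wrong way", {
  set.seed(99)
  strengths <- c("very_strong", "strong", "moderate", "supporting")
  for (i in 1:200) {
    cnt <- c(vs = sample(0:2, 1), s = sample(0:2, 1), m = sample(0:3, 1),
             p = sample(0:3, 1))
    base <- combine_evidence(profile_from_counts(cnt["vs"], cnt["s"],
                                                 cnt["m"], cnt["p"]))
    add <- sample(strengths, 1)
    slot <- c(very_strong = "vs", strong = "s", moderate = "m",
              supporting = "p")[add]
    cnt[slot] <- cnt[slot] + 1
    bigger <- combine_evidence(profile_from_counts(cnt["vs"], cnt["s"],
                                                   cnt["m"], cnt["p"]))
    expect_gte(TIER_ORDER[bigger$tier], TIER_ORDER[base$tier])
  }
  for (i in 1:200) {
    cnt <- c(sa = sample(0:1, 1), bs = sample(0:2, 1), bp = sample(0:3, 1))
    base <- combine_evidence(profile_from_counts(sa = cnt["sa"],
                                                 bs = cnt["bs"],
                                                 bp = cnt["bp"]))
    slot <- sample(c("sa", "bs", "bp"), 1)
    cnt[slot] <- cnt[slot] + 1
    bigger <- combine_evidence(profile_from_counts(sa = cnt["sa"],
                                                   bs = cnt["bs"],
                                                   bp = cnt["bp"]))
    expect_lte(TIER_ORDER[bigger$tier], TIER_ORDER[base$tier])
  }
})

test_that("combine is a pure function: identical profiles, identical output", {
  p <- table4_profile("c.1048G>A")
  a <- combine_evidence(p)
  b <- combine_evidence(p)
  expect_identical(a$tier, b$tier)
  expect_identical(a$rationale, b$rationale)
  expect_identical(a$matched_rule, b$matched_rule)
})

test_that("the VUS tier always carries a VUS rationale and vice versa", {
  set.seed(31)
  for (i in 1:300) {
    g <- sapply(c("vs", "s", "m", "p", "sa", "bs", "bp"),
                function(x) sample(0:3, 1))
    res <- combine_evidence(profile_from_counts(g["vs"], g["s"], g["m"],
                                                g["p"], g["sa"], g["bs"],
                                                g["bp"]))
    expect_identical(res$tier == "uncertain_significance",
                     res$rationale %in% c("insufficient_evidence",
                                          "evidence_in_conflict"))
  }
})
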