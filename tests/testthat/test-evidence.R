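# Evidence assigners: each code's threshold logic at VCEP strengths, the
# profile builder, and the assigners' invariants.

cal <- activity_calibration(gaa_control_panel())
prof <- vcep_profile()

test_that("PS3/BS3 follow the calibrated zones at the calibrated strength", {
  ps3 <- assign_ps3_bs3(10.7, cal)
  expect_equal(ps3$code, "PS3")
  expect_equal(ps3$applied_strength, "supporting")
  expect_equal(ps3$base_strength, "strong")
  expect_null(assign_ps3_bs3(11.7, cal))
  nd <- assign_ps3_bs3(activity_measurement(below_detection = TRUE), cal)
  expect_equal(format(nd), "PS3_supporting")
  bs3 <- assign_ps3_bs3(80, cal)
  expect_equal(bs3$code, "BS3")
  expect_equal(bs3$category, "benign")
  expect_error(assign_ps3_bs3(NULL, cal), "missing activity")
  expect_error(assign_ps3_bs3(NA_real_, cal), "missing activity")
})

test_that("moderate-strength calibration propagates into PS3", {
  cal_svi <- activity_calibration(gaa_control_panel(), policy = "svi")
  expect_equal(assign_ps3_bs3(2.8, cal_svi)$applied_strength, "moderate")
  expect_equal(assign_ps3_bs3(90, cal_svi)$applied_strength, "moderate")
})

test_that("PM2/BS1 apply strict frequency thresholds over all populations", {
  pm2 <- assign_pm2_bs1(NULL, prof)                 # absent
  expect_equal(format(pm2), "PM2_supporting")
  expect_equal(format(assign_pm2_bs1(numeric(0), prof)), "PM2_supporting")
  bs1 <- assign_pm2_bs1(c(south_asian = 0.006), prof)
  expect_equal(bs1$code, "BS1")
  expect_equal(bs1$applied_strength, "strong")
  expect_null(assign_pm2_bs1(c(european = 0.002), prof))
  # exactly at a threshold: no code (strict inequalities)
  expect_null(assign_pm2_bs1(c(global = 0.001), prof))
  expect_null(assign_pm2_bs1(c(global = 0.005), prof))
  # universal quantifier: one population above the PM2 bound blocks PM2
  expect_null(assign_pm2_bs1(c(a = 0.0001, b = 0.002), prof))
  expect_equal(assign_pm2_bs1(c(a = 0.00022, b = 0.0005), prof)$code, "PM2")
  expect_error(assign_pm2_bs1(c(a = 1.5), prof), "\\[0, 1\\]")
})

test_that("PM3 requires confirmed phase and records the partner", {
  pm3 <- assign_pm3(TRUE, "c.-32-13T>G", prof)
  expect_equal(pm3$code, "PM3")
  expect_equal(pm3$applied_strength, "moderate")
  expect_match(pm3$justification, "c\\.-32-13T>G")
  expect_match(assign_pm3(TRUE, "p.Glu530Glyfs*48", prof)$justification,
               "Glu530", fixed = TRUE)
  expect_null(assign_pm3(FALSE, "", prof))
})

test_that("PM5 demands a pathogenic missense change at the same codon", {
  pm5 <- assign_pm5(TRUE, "c.1124G>T (p.Arg375Leu)", prof)
  expect_equal(pm5$code, "PM5")
  expect_equal(pm5$applied_strength, "moderate")
  expect_null(assign_pm5(FALSE, "", prof))
  expect_error(assign_pm5(TRUE, "", prof), "PM5")
  expect_error(assign_pm5(TRUE, "c.2560C>T (p.Arg854*)", prof), "missense")
  expect_error(assign_pm5(TRUE, "p.Glu176Argfs*45", prof), "missense")
  expect_error(assign_pm5(TRUE, "p.Asp645=", prof), "missense")
})

test_that("PP3/BP4 apply strict REVEL thresholds with a no-call band", {
  expect_equal(assign_pp3_bp4(0.958, prof)$code, "PP3")
  expect_equal(assign_pp3_bp4(0.446, prof)$code, "BP4")
  expect_null(assign_pp3_bp4(0.566, prof))
  expect_null(assign_pp3_bp4(0.546, prof))
  expect_null(assign_pp3_bp4(0.7, prof))    # exactly at the PP3 threshold
  expect_null(assign_pp3_bp4(0.5, prof))    # exactly at the BP4 threshold
  expect_null(assign_pp3_bp4(NA, prof))
  expect_null(assign_pp3_bp4(NULL, prof))
  expect_error(assign_pp3_bp4(1.2, prof), "\\[0, 1\\]")
})

test_that("PP4 requires both the phenotype and pseudodeficiency exclusion", {
  pp4 <- assign_pp4(TRUE, TRUE, prof)
  expect_equal(format(pp4), "PP4_moderate")
  expect_null(assign_pp4(TRUE, FALSE, prof))
  expect_null(assign_pp4(FALSE, TRUE, prof))
})

test_that("profile invariants on the VCEP thresholds are enforced", {
  expect_error(vcep_profile(bp4_revel_max = 0.8), "below")
  expect_error(vcep_profile(pm2_af_max = 0.01), "below")
  expect_error(vcep_profile(pm2_strength = "huge"), "strength")
})

test_that("the profile builder reproduces the published per-variant code sets", {
  obs <- gaa_variant_observations()
  expected <- list(
    "c.316C>T"  = c("PS3", "PM2", "PM3", "PP4"),
    "c.1103G>A" = c("PS3", "PM2", "PM3", "PP4"),
    "c.1721T>C" = c("PS3", "PM2", "PM3", "PP3", "PP4"),
    "c.664G>A"  = c("BS1", "BP4", "PP4"),
    "c.2450A>G" = c("PS3", "PM2", "PP3", "PP4"),
    "c.1048G>A" = c("PS3", "PM2", "PM3", "PP3", "PP4"),
    "c.1378G>A" = c("PM2", "PM3", "PP4"),
    "c.1123C>T" = c("PM2", "PM3", "PM5", "PP3", "PP4")
  )
  for (i in seq_len(nrow(obs))) {
    ep <- build_evidence_profile(obs[i, ], cal, prof)
    codes <- vapply(ep$items, `[[`, character(1), "code")
    expect_equal(codes, expected[[obs$variant_cdna[i]]],
                 info = obs$variant_cdna[i])
  }
})

test_that("an uninformative observation yields an empty profile", {
  obs <- data.frame(variant_cdna = "c.1A>G", percent_wt = 20,
                    below_detection = FALSE, af_global = 0.002,
                    in_trans_pathogenic = FALSE, trans_partner = "",
                    same_codon_pathogenic = FALSE, same_codon_variant = "",
                    revel = 0.6, phenotype_consistent = FALSE,
                    pseudodeficiency_excluded = TRUE,
                    stringsAsFactors = FALSE)
  ep <- build_evidence_profile(obs, cal, prof)
  expect_length(ep, 0)
  expect_equal(combine_evidence(ep)$tier, "uncertain_significance")
})

test_that("profiles never contain mutually exclusive code pairs", {
  obs <- generate_observations(150, seed = 5, cal = cal, profile = prof)
  for (i in seq_len(nrow(obs))) {
    ep <- build_evidence_profile(obs[i, ], cal, prof)
    codes <- vapply(ep$items, `[[`, character(1), "code")
    expect_false(all(c("PM2", "BS1") %in% codes))
    expect_false(all(c("PP3", "BP4") %in% codes))
    expect_false(all(c("PS3", "BS3") %in% codes))
    expect_false(anyDuplicated(codes) > 0)
  }
})

test_that("assignment is monotone in REVEL and allele frequency", {
  revels <- sort(runif(40))
  had_pp3 <- FALSE
  for (r in revels) {
    it <- assign_pp3_bp4(r, prof)
    has_pp3 <- !is.null(it) && it$code == "PP3"
    if (had_pp3) expect_true(has_pp3)   # raising REVEL never removes PP3
    had_pp3 <- has_pp3
  }
  freqs <- sort(runif(40, 0, 0.02))
  had_bs1 <- FALSE
  for (f in freqs) {
    it <- assign_pm2_bs1(c(pop = f), prof)
    has_bs1 <- !is.null(it) && it$code == "BS1"
    if (had_bs1) expect_true(has_bs1)   # raising AF never removes BS1
    had_bs1 <- has_bs1
  }
})

test_that("the western-blot annotation never influences any evidence item", {
  obs <- gaa_variant_observations()
  bands <- c("precursor_and_mature", "precursor_only", "none_observed",
             "not_assayed")
  for (i in seq_len(nrow(obs))) {
    ref <- build_evidence_profile(obs[i, ], cal, prof)
    for (b in bands) {
      alt <- obs[i, ]
      alt$protein_bands <- b
      expect_identical(build_evidence_profile(alt, cal, prof), ref)
    }
  }
})
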