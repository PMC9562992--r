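# Calibration: zone boundaries from the control panel, strength policy,
# activity-zone classification, and the fit's S3 surface.

test_that("the validation panel calibrates to the published 11%/54% zones", {
  cal <- activity_calibration(gaa_control_panel())
  expect_s3_class(cal, "activity_calibration")
  expect_equal(cal$pathogenic_max, 11)
  expect_equal(cal$benign_min, 54)
  expect_equal(cal$n_pathogenic_controls, 7L)
  expect_equal(cal$n_benign_controls, 4L)
  expect_length(cal$warnings, 0)   # 17% sentinel sits inside the gap
  expect_equal(cal$ps3_strength, "supporting")
  expect_true(cal$ps3_applicable && cal$bs3_applicable)
  expect_equal(coef(cal), c(pathogenic_max = 11, benign_min = 54))
})

make_panel <- function(path, benign, pseudo = numeric(0)) {
  data.frame(
    variant_cdna = sprintf("c.%dA>G", seq_len(length(path) + length(benign) +
                                                length(pseudo))),
    known_class = c(rep("pathogenic", length(path)),
                    rep("benign", length(benign)),
                    rep("pseudodeficiency", length(pseudo))),
    percent_wt = c(path, benign, pseudo),
    below_detection = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("overlapping or incomplete panels are rejected", {
  expect_error(activity_calibration(make_panel(60, 54)), "not validatable")
  expect_error(activity_calibration(make_panel(54, 54)), "not validatable")
  expect_error(activity_calibration(make_panel(10, numeric(0))),
               "incomplete panel")
  expect_error(activity_calibration(make_panel(numeric(0), 90)),
               "incomplete panel")
  bad <- make_panel(c(5, 10), 90)
  bad$known_class[1] <- NA
  expect_error(activity_calibration(bad), "incomplete panel")
})

test_that("single-control extremes calibrate to their own activities", {
  cal <- activity_calibration(make_panel(0, 100))
  expect_equal(cal$pathogenic_max, 0)
  expect_equal(cal$benign_min, 100)
})

test_that("a pseudodeficiency control outside the gap raises a validation warning", {
  expect_warning(
    cal <- activity_calibration(make_panel(c(5, 11), 54, pseudo = 8)),
    "pseudodeficiency"
  )
  expect_length(cal$warnings, 1)
  # sentinel never moves the thresholds
  expect_equal(unname(coef(cal)), c(11, 54))
})

test_that("strength policy follows the SVI control-count rule", {
  expect_equal(determine_strength(7, 4, "conservative"),
               list(ps3 = "supporting", bs3 = "supporting"))
  expect_equal(determine_strength(7, 4, "svi"),
               list(ps3 = "moderate", bs3 = "moderate"))
  expect_equal(determine_strength(2, 0, "svi"),
               list(ps3 = "supporting", bs3 = "supporting"))
  expect_equal(determine_strength(10, 1, "svi")$ps3, "moderate")
  expect_equal(determine_strength(11, 0, "svi")$ps3, "supporting")
  expect_equal(determine_strength(6, 4, "svi")$ps3, "supporting")
})

test_that("adding controls never reduces strength under the svi policy", {
  rank <- c(supporting = 1, moderate = 2)
  for (np in 0:12) {
    for (nb in 0:12) {
      base <- rank[determine_strength(np, nb, "svi")$ps3]
      expect_gte(rank[determine_strength(np + 1, nb, "svi")$ps3], base)
      expect_gte(rank[determine_strength(np, nb + 1, "svi")$ps3], base)
    }
  }
})

test_that("zone boundaries are strict below, inclusive above", {
  cal <- activity_calibration(gaa_control_panel())
  expect_equal(as.character(classify_activity(2.8, cal)), "pathogenic_range")
  expect_equal(as.character(classify_activity(10.7, cal)), "pathogenic_range")
  expect_equal(as.character(classify_activity(11.0, cal)), "indeterminate")
  expect_equal(as.character(classify_activity(17, cal)), "indeterminate")
  expect_equal(as.character(classify_activity(53.999, cal)), "indeterminate")
  expect_equal(as.character(classify_activity(54, cal)), "benign_range")
  expect_equal(as.character(classify_activity(100, cal)), "benign_range")
})

test_that("below-detection always classifies into the pathogenic range", {
  cal <- activity_calibration(gaa_control_panel())
  expect_equal(as.character(classify_activity(0, cal, below_detection = TRUE)),
               "pathogenic_range")
  nd <- activity_measurement(below_detection = TRUE)
  expect_equal(as.character(classify_activity(nd, cal)), "pathogenic_range")
  # even when the pathogenic bound is 0 (strict < would otherwise exclude 0)
  cal0 <- activity_calibration(make_panel(0, 100))
  expect_equal(as.character(classify_activity(0, cal0, below_detection = TRUE)),
               "pathogenic_range")
  expect_equal(as.character(classify_activity(0, cal0)), "indeterminate")
})

test_that("controls are self-consistent under their own calibration", {
  # pathogenic controls sit at or below the bound (strictly-below ones in
  # the pathogenic range); benign controls all sit in the benign range
  set.seed(101)
  for (i in 1:20) {
    panel <- generate_panel(panel_spec(seed = i, replicate_sd = 1))
    # sentinel may drift outside the gap under noise; not under test here
    cal <- suppressWarnings(activity_calibration(panel))
    act <- cal$controls$activity
    cls <- cal$controls$known_class
    zones <- as.character(classify_activity(act, cal))
    path <- cls == "pathogenic"
    ben <- cls %in% c("benign", "likely_benign")
    expect_true(all(act[path] <= cal$pathogenic_max))
    expect_true(all(zones[path & act < cal$pathogenic_max] ==
                      "pathogenic_range"))
    expect_true(all(zones[ben] == "benign_range"))
  }
})

test_that("predict() classifies new data frames and numeric vectors", {
  cal <- activity_calibration(gaa_control_panel())
  expect_equal(as.character(predict(cal, c(2.8, 17, 80))),
               c("pathogenic_range", "indeterminate", "benign_range"))
  expect_equal(predict(cal, c(2.8, 17, 80), type = "evidence"),
               c("PS3_supporting", NA, "BS3_supporting"))
  newdata <- data.frame(rep1 = c(11.05, 18.9), rep2 = c(10.35, 16),
                        below_detection = c(FALSE, FALSE))
  expect_equal(as.character(predict(cal, newdata)),
               c("pathogenic_range", "indeterminate"))
  # default: the fitted controls
  expect_length(predict(cal), nrow(gaa_control_panel()))
})

test_that("print and summary render without error", {
  cal <- activity_calibration(gaa_control_panel())
  expect_output(print(cal), "pathogenic zone")
  expect_output(print(summary(cal)), "Control panel")
})
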