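# End-to-end orchestration: calibrate from a control panel, assign
# evidence per tested variant, combine, and emit a report table with the
# full audit trail -- activity zone, each code decision, final tier,
# rationale, matched rule, and the counterfactual tier without the
# functional-assay evidence.

#' Classify observed variants against a calibration
#'
#' For each observation row, builds the evidence profile
#' ([build_evidence_profile()]), combines it ([combine_evidence()]), and
#' records every intermediate decision. A counterfactual column reports
#' the tier with PS3/BS3 removed, quantifying the functional assay's
#' contribution per variant.
#'
#' @param observations data.frame of observations
#'   ([read_observations_tsv()] layout).
#' @param cal an [activity_calibration()] fit.
#' @param profile a [vcep_profile()].
#' @param ablation include the tier-without-functional-evidence column?
#' @param logger optional function called with one audit line per evidence
#'   decision (e.g. `message`); `NULL` disables logging.
#' @return a `"variant_report"`: a data.frame, one row per input variant
#'   (input order), with attributes `calibration`, `profile`, `profiles`
#'   (the per-variant [evidence_profile()] list), `generated_at` and
#'   `package_version`.
#' @examples
#' cal <- activity_calibration(gaa_control_panel())
#' report <- classify_variants(gaa_variant_observations(), cal)
#' report[, c("variant_cdna", "final_tier", "rationale")]
#' @export
classify_variants <- function(observations, cal, profile = vcep_profile(),
                              ablation = TRUE, logger = NULL) {
  stopifnot(is.data.frame(observations), inherits(cal, "activity_calibration"))
  rows <- vector("list", nrow(observations))
  profiles <- vector("list", nrow(observations))
  for (i in seq_len(nrow(observations))) {
    obs <- observations[i, , drop = FALSE]
    ep <- build_evidence_profile(obs, cal, profile)
    profiles[[i]] <- ep
    cls <- combine_evidence(ep)

    bd <- isTRUE(obs$below_detection)
    reps <- as.numeric(obs[1, rep_cols(obs)])
    reps <- reps[!is.na(reps)]
    pct <- if (bd) NA_real_
           else if (length(reps)) mean(reps)
           else as.numeric(obs$percent_wt)
    zone <- as.character(classify_activity(if (bd) 0 else pct, cal, bd))

    codes <- profile_codes(ep)
    fmts <- vapply(ep$items, format, character(1))
    code_of <- function(want) {
      hit <- which(codes %in% want)
      if (length(hit)) fmts[hit[1]] else NA_character_
    }

    counterfactual <- ablate(ep, c("PS3", "BS3"))
    note <- if (cls$tier == "uncertain_significance" &&
                zone == "indeterminate") {
      "functional evidence not applicable: activity in the indeterminate zone"
    } else {
      ""
    }

    if (!is.null(logger)) {
      for (k in seq_along(ep$items)) {
        it <- ep$items[[k]]
        logger(sprintf("variant=%s code=%s strength=%s reason=%s",
                       obs$variant_cdna, it$code, it$applied_strength,
                       it$justification))
      }
      logger(sprintf("variant=%s tier=%s rationale=%s rule=%s",
                     obs$variant_cdna, cls$tier, cls$rationale,
                     cls$matched_rule))
    }

    rows[[i]] <- data.frame(
      variant_cdna = obs$variant_cdna,
      variant_protein = if (!is.null(obs$variant_protein))
        obs$variant_protein else "",
      percent_wt = pct,
      percent_wt_display = if (bd) NA_real_ else round_half_away(pct, 1L),
      below_detection = bd,
      activity_zone = zone,
      ps3_bs3 = code_of(c("PS3", "BS3")),
      pm2_bs1 = code_of(c("PM2", "BS1")),
      pm3 = code_of("PM3"),
      pm5 = code_of("PM5"),
      pp3_bp4 = code_of(c("PP3", "BP4")),
      pp4 = code_of("PP4"),
      protein_bands = if (!is.null(obs$protein_bands))
        obs$protein_bands else "not_assayed",
      evidence = format(ep),
      final_tier = cls$tier,
      rationale = cls$rationale,
      matched_rule = cls$matched_rule,
      tier_without_functional = if (ablation) counterfactual$tier
        else NA_character_,
      note = note,
      stringsAsFactors = FALSE
    )
  }
  report <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(variant_cdna = character(0),
                         variant_protein = character(0),
                         percent_wt = numeric(0),
                         percent_wt_display = numeric(0),
                         below_detection = logical(0),
                         activity_zone = character(0),
                         ps3_bs3 = character(0), pm2_bs1 = character(0),
                         pm3 = character(0), pm5 = character(0),
                         pp3_bp4 = character(0), pp4 = character(0),
                         protein_bands = character(0),
                         evidence = character(0),
                         final_tier = character(0), rationale = character(0),
                         matched_rule = character(0),
                         tier_without_functional = character(0),
                         note = character(0), stringsAsFactors = FALSE)
  }
  structure(report,
            class = c("variant_report", "data.frame"),
            calibration = cal, profile = profile, profiles = profiles,
            generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            package_version = as.character(utils::packageVersion("gaavcep")))
}

#' @export
`[.variant_report` <- function(x, ...) {
  # column subsets are ordinary data.frames; the report print layout
  # assumes the full column set
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.variant_report <- function(x, ...) {
  cal <- attr(x, "calibration")
  cat(sprintf("GAA variant classification report (%d variants)\n", nrow(x)))
  cat(sprintf("  calibration: pathogenic < %g%%, benign >= %g%%, PS3_%s/BS3_%s (%s policy)\n",
              cal$pathogenic_max, cal$benign_min, cal$ps3_strength,
              cal$bs3_strength, cal$policy))
  if (nrow(x) == 0L) return(invisible(x))
  shown <- data.frame(
    variant = ifelse(nzchar(x$variant_protein),
                     paste0(x$variant_cdna, " (", x$variant_protein, ")"),
                     x$variant_cdna),
    activity = ifelse(x$below_detection, "ND",
                      sprintf("%.1f%%", x$percent_wt_display)),
    zone = sub("_range", "", x$activity_zone),
    evidence = x$evidence,
    classification = paste0(TIER_LABELS[x$final_tier], " (",
                            RATIONALE_LABELS[x$rationale], ")"),
    stringsAsFactors = FALSE
  )
  print(shown, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
summary.variant_report <- function(object, ...) {
  tab <- table(factor(object$final_tier, levels = names(TIER_LABELS)))
  cat("Final classifications:\n")
  for (t in names(tab)) {
    if (tab[[t]]) cat(sprintf("  %-22s %d\n", TIER_LABELS[[t]], tab[[t]]))
  }
  flips <- sum(object$final_tier != object$tier_without_functional,
               na.rm = TRUE)
  cat(sprintf("Variants whose tier depends on the functional assay: %d\n",
              flips))
  invisible(tab)
}

#' Run the full classification pipeline from files
#'
#' Reads the control panel, calibrates the assay, reads the tested-variant
#' observations and the VCEP profile, classifies every variant, and
#' optionally writes the report as TSV and/or JSON.
#'
#' @param controls_path controls TSV ([read_controls_tsv()]).
#' @param variants_path observations TSV ([read_observations_tsv()]).
#' @param profile_path VCEP profile JSON, or `NULL` for VCEP defaults.
#' @param policy calibration strength policy (see
#'   [activity_calibration()]).
#' @param out_tsv,out_json optional output paths.
#' @param logger optional audit logger (see [classify_variants()]).
#' @return a `"variant_report"` (invisibly when writing output).
#' @examples
#' paths <- write_study_fixtures(tempfile("fx"))
#' report <- run_pipeline(paths[["controls"]], paths[["observations"]])
#' summary(report)
#' @export
run_pipeline <- function(controls_path, variants_path, profile_path = NULL,
                         policy = c("conservative", "svi"),
                         out_tsv = NULL, out_json = NULL, logger = NULL) {
  policy <- match.arg(policy)
  controls <- read_controls_tsv(controls_path)
  cal <- activity_calibration(controls, policy = policy)
  observations <- read_observations_tsv(variants_path)
  profile <- if (is.null(profile_path)) vcep_profile()
             else read_vcep_profile(profile_path)
  report <- classify_variants(observations, cal, profile, logger = logger)
  if (!is.null(out_tsv)) write_report_tsv(report, out_tsv)
  if (!is.null(out_json)) write_report_json(report, out_json)
  if (is.null(out_tsv) && is.null(out_json)) report else invisible(report)
}

#' Write a classification report as TSV or JSON
#'
#' The TSV holds the report rows; the JSON twin adds the header metadata
#' (calibration summary, profile thresholds, package version, timestamp).
#'
#' @param report a `"variant_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  write_tsv_plain(as.data.frame(report), path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  cal <- attr(report, "calibration")
  doc <- list(
    metadata = list(
      generated_at = attr(report, "generated_at"),
      package_version = attr(report, "package_version"),
      calibration = list(pathogenic_max = cal$pathogenic_max,
                         benign_min = cal$benign_min,
                         ps3_strength = cal$ps3_strength,
                         bs3_strength = cal$bs3_strength,
                         policy = cal$policy),
      profile = unclass(attr(report, "profile"))
    ),
    variants = as.data.frame(report)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}
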