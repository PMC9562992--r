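# ACMG/AMP evidence-code assignment at ClinGen GAA VCEP strengths.
#
# Each assigner maps one observation (activity zone, allele frequency,
# phase, co-located variant, REVEL score, phenotype) to at most one
# evidence item. All threshold comparisons are strict, matching the VCEP
# specification (PP3 requires REVEL > 0.7, BP4 requires < 0.5; PM2
# requires all population frequencies < 0.001, BS1 any frequency > 0.005);
# a value exactly at a threshold yields no code.

STRENGTH_LEVELS <- c("stand_alone", "very_strong", "strong", "moderate",
                     "supporting")

#' VCEP threshold profile
#'
#' The gene-specific numeric thresholds and strength modifications used by
#' the evidence assigners. Defaults are the ClinGen GAA VCEP values:
#' PM2 below 0.001 (applied as supporting), BS1 above 0.005, PP3 above a
#' REVEL of 0.7, BP4 below 0.5, PP4 at moderate, PM3 and PM5 at moderate.
#'
#' @param pm2_af_max maximum allele frequency (exclusive) in every
#'   population for PM2.
#' @param bs1_af_min minimum allele frequency (exclusive) in any
#'   population for BS1.
#' @param pp3_revel_min REVEL score (exclusive) above which PP3 applies.
#' @param bp4_revel_max REVEL score (exclusive) below which BP4 applies.
#' @param pm2_strength,pp4_strength,pm3_strength,pm5_strength applied
#'   strengths for the modifiable codes.
#' @return an object of class `"vcep_profile"`.
#' @examples
#' vcep_profile()
#' @export
vcep_profile <- function(pm2_af_max = 0.001, bs1_af_min = 0.005,
                         pp3_revel_min = 0.7, bp4_revel_max = 0.5,
                         pm2_strength = "supporting",
                         pp4_strength = "moderate",
                         pm3_strength = "moderate",
                         pm5_strength = "moderate") {
  stopifnot(pm2_af_max >= 0, pm2_af_max <= 1, bs1_af_min >= 0, bs1_af_min <= 1,
            pp3_revel_min >= 0, pp3_revel_min <= 1,
            bp4_revel_max >= 0, bp4_revel_max <= 1)
  if (bp4_revel_max >= pp3_revel_min) {
    stop("bp4_revel_max must be below pp3_revel_min", call. = FALSE)
  }
  if (pm2_af_max >= bs1_af_min) {
    stop("pm2_af_max must be below bs1_af_min", call. = FALSE)
  }
  for (s in c(pm2_strength, pp4_strength, pm3_strength, pm5_strength)) {
    if (!s %in% STRENGTH_LEVELS) {
      stop(sprintf("unknown strength '%s'", s), call. = FALSE)
    }
  }
  structure(
    list(pm2_af_max = pm2_af_max, bs1_af_min = bs1_af_min,
         pp3_revel_min = pp3_revel_min, bp4_revel_max = bp4_revel_max,
         pm2_strength = pm2_strength, pp4_strength = pp4_strength,
         pm3_strength = pm3_strength, pm5_strength = pm5_strength),
    class = "vcep_profile"
  )
}

#' @export
print.vcep_profile <- function(x, ...) {
  cat("VCEP criteria profile\n")
  cat(sprintf("  PM2_%s: AF < %g in all populations; BS1: AF > %g in any\n",
              x$pm2_strength, x$pm2_af_max, x$bs1_af_min))
  cat(sprintf("  PP3: REVEL > %g; BP4: REVEL < %g\n",
              x$pp3_revel_min, x$bp4_revel_max))
  cat(sprintf("  PM3_%s, PM5_%s, PP4_%s\n",
              x$pm3_strength, x$pm5_strength, x$pp4_strength))
  invisible(x)
}

#' Construct a single evidence item
#'
#' @param code ACMG/AMP code, e.g. `"PS3"`, `"PM2"`, `"BS1"`. Codes
#'   starting with P are pathogenic-category, with B benign-category.
#' @param base_strength the code's default strength on the ACMG scale.
#' @param applied_strength the strength at which it is applied here
#'   (defaults to `base_strength`; VCEP modifications pass a different
#'   value, e.g. PS3 applied as supporting).
#' @param justification free-text audit note.
#' @return an object of class `"evidence_item"`.
#' @export
evidence_item <- function(code, base_strength,
                          applied_strength = base_strength,
                          justification = "") {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  category <- if (grepl("^P", code)) "pathogenic"
              else if (grepl("^B", code)) "benign"
              else stop(sprintf("cannot infer category for code '%s'", code),
                        call. = FALSE)
  for (s in c(base_strength, applied_strength)) {
    if (!s %in% STRENGTH_LEVELS) {
      stop(sprintf("unknown strength '%s'", s), call. = FALSE)
    }
  }
  structure(
    list(code = code, category = category, base_strength = base_strength,
         applied_strength = applied_strength, justification = justification),
    class = "evidence_item"
  )
}

#' @export
format.evidence_item <- function(x, ...) {
  if (x$applied_strength != x$base_strength ||
      x$code %in% c("PM2", "PP4")) {
    paste0(x$code, "_", x$applied_strength)
  } else {
    x$code
  }
}

#' @export
print.evidence_item <- function(x, ...) {
  cat(format(x), if (nzchar(x$justification)) paste0(" -- ", x$justification),
      "\n", sep = "")
  invisible(x)
}

#' Functional evidence (PS3/BS3) from the calibrated assay
#'
#' Activity in the pathogenic zone yields PS3 at the calibrated strength;
#' activity in the benign zone yields BS3; the indeterminate zone yields
#' no functional evidence at any strength.
#'
#' @param activity an [activity_measurement()], or a single % wild-type
#'   value.
#' @param cal an [activity_calibration()] fit.
#' @param below_detection logical, used when `activity` is numeric.
#' @return an [evidence_item()] or `NULL`.
#' @examples
#' cal <- activity_calibration(gaa_control_panel())
#' assign_ps3_bs3(10.7, cal)   # PS3_supporting
#' assign_ps3_bs3(11.7, cal)   # NULL: indeterminate
#' @export
assign_ps3_bs3 <- function(activity, cal, below_detection = FALSE) {
  stopifnot(inherits(cal, "activity_calibration"))
  if (is.null(activity)) stop("missing activity measurement", call. = FALSE)
  if (inherits(activity, "activity_measurement")) {
    below_detection <- activity$below_detection
    pct <- if (below_detection) 0 else activity$percent_wt
  } else {
    pct <- as.numeric(activity)
    if (length(pct) != 1L || (is.na(pct) && !below_detection)) {
      stop("missing activity measurement", call. = FALSE)
    }
    if (below_detection) pct <- 0
  }
  zone <- as.character(classify_activity(pct, cal, below_detection))
  shown <- if (below_detection) "not detectable" else sprintf("%g%% WT", pct)
  if (zone == "pathogenic_range" && cal$ps3_applicable) {
    evidence_item("PS3", "strong", cal$ps3_strength,
                  sprintf("activity %s is below the pathogenic-control maximum (%g%%)",
                          shown, cal$pathogenic_max))
  } else if (zone == "benign_range" && cal$bs3_applicable) {
    evidence_item("BS3", "strong", cal$bs3_strength,
                  sprintf("activity %s is at or above the benign-control minimum (%g%%)",
                          shown, cal$benign_min))
  } else {
    NULL
  }
}

#' Population-frequency evidence (PM2/BS1)
#'
#' BS1 applies when any population frequency exceeds the BS1 threshold;
#' otherwise PM2 applies when the variant is absent (empty frequency map)
#' or every provided population frequency is below the PM2 threshold.
#'
#' @param af named numeric vector of per-population allele frequencies;
#'   `NULL`, empty, or all-`NA` means absent from population databases.
#' @param profile a [vcep_profile()].
#' @return an [evidence_item()] or `NULL`.
#' @examples
#' assign_pm2_bs1(NULL, vcep_profile())                      # PM2_supporting
#' assign_pm2_bs1(c(south_asian = 0.006), vcep_profile())    # BS1
#' assign_pm2_bs1(c(european = 0.002), vcep_profile())       # NULL
#' @export
assign_pm2_bs1 <- function(af, profile = vcep_profile()) {
  stopifnot(inherits(profile, "vcep_profile"))
  af <- af[!is.na(af)]
  if (length(af) && (any(af < 0) || any(af > 1))) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (length(af) && any(af > profile$bs1_af_min)) {
    pops <- names(af)[af > profile$bs1_af_min]
    pops <- if (is.null(pops)) "a population" else paste(pops, collapse = ", ")
    evidence_item("BS1", "strong",
                  justification = sprintf("allele frequency > %g (%s)",
                                          profile$bs1_af_min, pops))
  } else if (length(af) == 0L) {
    evidence_item("PM2", "moderate", profile$pm2_strength,
                  "absent from population databases")
  } else if (all(af < profile$pm2_af_max)) {
    evidence_item("PM2", "moderate", profile$pm2_strength,
                  sprintf("allele frequency < %g in all provided populations",
                          profile$pm2_af_max))
  } else {
    NULL
  }
}

#' In-trans evidence (PM3)
#'
#' Applies when the variant was confirmed in trans with a pathogenic
#' variant (recessive disease); the flag must only be set with parental or
#' equivalent phase data.
#'
#' @param in_trans_pathogenic logical.
#' @param partner cDNA or protein name of the in-trans pathogenic variant
#'   (audit trail only).
#' @param profile a [vcep_profile()].
#' @return an [evidence_item()] or `NULL`.
#' @export
assign_pm3 <- function(in_trans_pathogenic, partner = "",
                       profile = vcep_profile()) {
  if (!isTRUE(in_trans_pathogenic)) return(NULL)
  just <- if (!is.null(partner) && !is.na(partner) && nzchar(partner)) {
    sprintf("in trans with pathogenic variant %s (phase confirmed)", partner)
  } else {
    "in trans with a pathogenic variant (phase confirmed)"
  }
  evidence_item("PM3", "moderate", profile$pm3_strength, just)
}

# missense protein-change pattern: p.Xxx123Yyy (optionally parenthesized),
# excluding Ter/fs/del/dup/=/synonymous forms
is_missense_protein <- function(p) {
  p <- gsub("[()]", "", trimws(p))
  grepl("^p\\.[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}$", p) &
    !grepl("Ter$|fs|del|dup|=", p)
}

#' Same-codon evidence (PM5)
#'
#' Applies when a *different missense* change at the same codon is
#' established pathogenic. The cited variant must itself be missense;
#' citing a truncating or synonymous change is an error.
#'
#' @param same_codon_pathogenic logical.
#' @param other_variant protein (or "cdna (protein)") name of the cited
#'   pathogenic missense variant; required when the flag is `TRUE`.
#' @param profile a [vcep_profile()].
#' @return an [evidence_item()] or `NULL`.
#' @examples
#' assign_pm5(TRUE, "c.1124G>T (p.Arg375Leu)")
#' @export
assign_pm5 <- function(same_codon_pathogenic, other_variant = "",
                       profile = vcep_profile()) {
  if (!isTRUE(same_codon_pathogenic)) return(NULL)
  if (is.null(other_variant) || is.na(other_variant) || !nzchar(other_variant)) {
    stop("PM5 requires naming the pathogenic missense variant at the same codon",
         call. = FALSE)
  }
  prot <- regmatches(other_variant,
                     regexpr("p\\.[A-Za-z0-9=*()]+", other_variant))
  if (length(prot) == 0L || !is_missense_protein(prot)) {
    stop(sprintf("PM5 precondition violated: '%s' is not a missense protein change",
                 other_variant), call. = FALSE)
  }
  evidence_item("PM5", "moderate", profile$pm5_strength,
                sprintf("different pathogenic missense variant at same codon: %s",
                        other_variant))
}

#' In-silico evidence (PP3/BP4) from a REVEL score
#'
#' PP3 applies strictly above the VCEP REVEL threshold, BP4 strictly below
#' the BP4 threshold; scores between the thresholds (or missing) yield no
#' code.
#'
#' @param revel REVEL score in \[0, 1\], or `NA`/`NULL` when unavailable.
#' @param profile a [vcep_profile()].
#' @return an [evidence_item()] or `NULL`.
#' @examples
#' assign_pp3_bp4(0.958)  # PP3
#' assign_pp3_bp4(0.446)  # BP4
#' assign_pp3_bp4(0.566)  # NULL
#' @export
assign_pp3_bp4 <- function(revel, profile = vcep_profile()) {
  if (is.null(revel) || length(revel) == 0L || is.na(revel)) return(NULL)
  if (revel < 0 || revel > 1) {
    stop("REVEL score must lie in [0, 1]", call. = FALSE)
  }
  if (revel > profile$pp3_revel_min) {
    evidence_item("PP3", "supporting",
                  justification = sprintf("REVEL %g > %g", revel,
                                          profile$pp3_revel_min))
  } else if (revel < profile$bp4_revel_max) {
    evidence_item("BP4", "supporting",
                  justification = sprintf("REVEL %g < %g", revel,
                                          profile$bp4_revel_max))
  } else {
    NULL
  }
}

#' Phenotype evidence (PP4)
#'
#' Applies only when the clinical presentation is specific for Pompe
#' disease (deficient GAA activity in blood with a consistent phenotype)
#' *and* pseudodeficiency alleles have been excluded by sequencing --
#' without the exclusion, low blood GAA activity is not interpretable.
#'
#' @param phenotype_consistent logical.
#' @param pseudodeficiency_excluded logical.
#' @param profile a [vcep_profile()].
#' @return an [evidence_item()] or `NULL`.
#' @export
assign_pp4 <- function(phenotype_consistent, pseudodeficiency_excluded,
                       profile = vcep_profile()) {
  if (!isTRUE(phenotype_consistent) || !isTRUE(pseudodeficiency_excluded)) {
    return(NULL)
  }
  evidence_item("PP4", "supporting", profile$pp4_strength,
                "GAA deficiency with Pompe-consistent phenotype; pseudodeficiency alleles excluded")
}

#' Build the full evidence profile for one observed variant
#'
#' Runs every assigner (PS3/BS3, PM2/BS1, PM3, PM5, PP3/BP4, PP4) on a
#' one-row observation and collects the applicable items. The western-blot
#' `protein_bands` annotation is deliberately never consulted: it is
#' carried into reports for review only.
#'
#' @param obs a one-row data.frame (or list) with the observation fields of
#'   [read_observations_tsv()], or an element of
#'   [gaa_variant_observations()].
#' @param cal an [activity_calibration()] fit.
#' @param profile a [vcep_profile()].
#' @return an [evidence_profile()].
#' @examples
#' cal <- activity_calibration(gaa_control_panel())
#' obs <- gaa_variant_observations()[1, ]
#' build_evidence_profile(obs, cal)
#' @export
build_evidence_profile <- function(obs, cal, profile = vcep_profile()) {
  obs <- as.list(obs)
  reps <- as.numeric(unlist(obs[grep("^rep[0-9]+$", names(obs))]))
  reps <- reps[!is.na(reps)]
  bd <- isTRUE(obs$below_detection)
  m <- if (bd) {
    activity_measurement(below_detection = TRUE)
  } else if (length(reps)) {
    activity_measurement(replicates = reps)
  } else if (!is.null(obs$percent_wt) && !is.na(obs$percent_wt)) {
    activity_measurement(percent_wt = obs$percent_wt)
  } else {
    stop(sprintf("variant '%s': no activity data", obs$variant_cdna),
         call. = FALSE)
  }
  afn <- grep("^af_", names(obs), value = TRUE)
  af <- stats::setNames(as.numeric(unlist(obs[afn])), sub("^af_", "", afn))
  items <- list(
    assign_ps3_bs3(m, cal),
    assign_pm2_bs1(af, profile),
    assign_pm3(obs$in_trans_pathogenic, obs$trans_partner, profile),
    assign_pm5(obs$same_codon_pathogenic, obs$same_codon_variant, profile),
    assign_pp3_bp4(obs$revel, profile),
    assign_pp4(obs$phenotype_consistent, obs$pseudodeficiency_excluded, profile)
  )
  evidence_profile(items = Filter(Negate(is.null), items))
}
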