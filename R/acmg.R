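# The ACMG/AMP evidence-combination engine (2015 standard), applied to
# items whose strengths may have been modified per VCEP specification: a
# code counts in the slot of its *applied* strength, so PS3 applied as
# supporting increments the supporting count, and PP4 applied as moderate
# increments the moderate count.
#
# Benign evidence uses the stand-alone / strong / supporting slots of the
# standard; under unrestricted strength substitution a benign item carrying
# very_strong counts as strong and one carrying moderate counts as
# supporting (the standard defines no benign slots between those).

#' Evidence profile: the set of codes applied to one variant
#'
#' @param ... [evidence_item()] objects, or a single list of them via
#'   `items`.
#' @param items optional list of [evidence_item()]s.
#' @return an object of class `"evidence_profile"`; duplicate codes are an
#'   error.
#' @examples
#' evidence_profile(
#'   evidence_item("PS3", "strong", "supporting"),
#'   evidence_item("PM2", "moderate", "supporting"),
#'   evidence_item("PM3", "moderate"),
#'   evidence_item("PP4", "supporting", "moderate")
#' )
#' @export
evidence_profile <- function(..., items = NULL) {
  if (is.null(items)) items <- list(...)
  ok <- vapply(items, inherits, logical(1), what = "evidence_item")
  if (!all(ok)) stop("all profile entries must be evidence items", call. = FALSE)
  codes <- vapply(items, `[[`, character(1), "code")
  if (anyDuplicated(codes)) {
    stop(sprintf("duplicate evidence code '%s' in profile",
                 codes[duplicated(codes)][1]), call. = FALSE)
  }
  structure(list(items = items), class = "evidence_profile")
}

#' @export
format.evidence_profile <- function(x, ...) {
  if (length(x$items) == 0L) return("(no evidence)")
  paste(vapply(x$items, format, character(1)), collapse = ", ")
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat("Evidence profile:", format(x), "\n")
  invisible(x)
}

#' @export
length.evidence_profile <- function(x) length(x$items)

profile_codes <- function(profile) {
  vapply(profile$items, `[[`, character(1), "code")
}

#' Tally evidence items into strength-slot counts
#'
#' @param profile an [evidence_profile()].
#' @return named integer vector with pathogenic slots `vs`, `s`, `m`, `p`
#'   (very strong, strong, moderate, supporting) and benign slots `sa`,
#'   `bs`, `bp` (stand-alone, strong, supporting), plus `has_pathogenic` /
#'   `has_benign` presence flags as attributes.
#' @export
strength_counts <- function(profile) {
  stopifnot(inherits(profile, "evidence_profile"))
  counts <- c(vs = 0L, s = 0L, m = 0L, p = 0L, sa = 0L, bs = 0L, bp = 0L)
  has_path <- FALSE; has_ben <- FALSE
  for (it in profile$items) {
    if (it$category == "pathogenic") {
      has_path <- TRUE
      slot <- switch(it$applied_strength,
                     stand_alone = ,       # no pathogenic stand-alone slot
                     very_strong = "vs",
                     strong = "s", moderate = "m", supporting = "p")
      counts[slot] <- counts[slot] + 1L
    } else {
      has_ben <- TRUE
      slot <- switch(it$applied_strength,
                     stand_alone = "sa",
                     very_strong = ,
                     strong = "bs",
                     moderate = ,
                     supporting = "bp")
      counts[slot] <- counts[slot] + 1L
    }
  }
  structure(counts, has_pathogenic = has_path, has_benign = has_ben)
}

# First pathogenic-side rule satisfied (P before LP), or NA.
# Returns c(tier, rule_id).
pathogenic_rule <- function(vs, s, m, p) {
  if (vs >= 1 && (s >= 1 || m >= 2 || (m == 1 && p == 1) || p >= 2)) {
    return(c("pathogenic", "P:VS+1"))
  }
  if (s >= 2) return(c("pathogenic", "P:2S"))
  if (s == 1 && (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4))) {
    return(c("pathogenic", "P:S+M/P"))
  }
  if (vs == 1 && m == 1) return(c("likely_pathogenic", "LP:VS+M"))
  if (s == 1 && m >= 1 && m <= 2) return(c("likely_pathogenic", "LP:S+1-2M"))
  if (s == 1 && p >= 2) return(c("likely_pathogenic", "LP:S+2P"))
  if (m >= 3) return(c("likely_pathogenic", "LP:3M"))
  if (m == 2 && p >= 2) return(c("likely_pathogenic", "LP:2M+2P"))
  if (m == 1 && p >= 4) return(c("likely_pathogenic", "LP:M+4P"))
  NULL
}

benign_rule <- function(sa, bs, bp) {
  if (sa >= 1) return(c("benign", "B:SA"))
  if (bs >= 2) return(c("benign", "B:2BS"))
  if (bs == 1 && bp >= 1) return(c("likely_benign", "LB:BS+BP"))
  if (bp >= 2) return(c("likely_benign", "LB:2BP"))
  NULL
}

#' Combine an evidence profile into a final classification
#'
#' Applies the ACMG/AMP combining rules over the strength-slot counts (at
#' each item's *applied* strength). When items of both categories are
#' present and either side on its own satisfies a non-VUS rule, the result
#' is uncertain significance with rationale `evidence_in_conflict`; when
#' neither side satisfies any rule, uncertain significance with
#' `insufficient_evidence`.
#'
#' @param profile an [evidence_profile()].
#' @return an object of class `"acmg_classification"`: list with `tier`
#'   (pathogenic / likely_pathogenic / uncertain_significance /
#'   likely_benign / benign), `rationale` (no_conflict /
#'   insufficient_evidence / evidence_in_conflict) and `matched_rule`
#'   (identifier of the satisfied combining rule, or `NA`).
#' @examples
#' p1 <- evidence_profile(
#'   evidence_item("PS3", "strong", "supporting"),
#'   evidence_item("PM2", "moderate", "supporting"),
#'   evidence_item("PM3", "moderate"),
#'   evidence_item("PP4", "supporting", "moderate")
#' )
#' combine_evidence(p1)   # likely pathogenic: 2 moderate + 2 supporting
#' @export
combine_evidence <- function(profile) {
  cnt <- strength_counts(profile)
  path <- pathogenic_rule(cnt[["vs"]], cnt[["s"]], cnt[["m"]], cnt[["p"]])
  ben <- benign_rule(cnt[["sa"]], cnt[["bs"]], cnt[["bp"]])
  has_both <- attr(cnt, "has_pathogenic") && attr(cnt, "has_benign")

  if (has_both && (!is.null(path) || !is.null(ben))) {
    rules <- paste(c(path[2], ben[2]), collapse = " vs ")
    res <- list(tier = "uncertain_significance",
                rationale = "evidence_in_conflict",
                matched_rule = rules)
  } else if (!is.null(path)) {
    res <- list(tier = path[1], rationale = "no_conflict",
                matched_rule = path[2])
  } else if (!is.null(ben)) {
    res <- list(tier = ben[1], rationale = "no_conflict",
                matched_rule = ben[2])
  } else {
    res <- list(tier = "uncertain_significance",
                rationale = "insufficient_evidence",
                matched_rule = NA_character_)
  }
  res$counts <- cnt
  res$profile <- profile
  structure(res, class = "acmg_classification")
}

TIER_LABELS <- c(pathogenic = "Pathogenic",
                 likely_pathogenic = "Likely pathogenic",
                 uncertain_significance = "VUS",
                 likely_benign = "Likely benign",
                 benign = "Benign")

RATIONALE_LABELS <- c(no_conflict = "No conflict",
                      insufficient_evidence = "Insufficient evidence",
                      evidence_in_conflict = "Evidence in conflict")

#' @export
print.acmg_classification <- function(x, ...) {
  cat(sprintf("%s (%s)\n", TIER_LABELS[[x$tier]],
              RATIONALE_LABELS[[x$rationale]]))
  if (!is.na(x$matched_rule)) cat("  rule:", x$matched_rule, "\n")
  cat("  evidence:", format(x$profile), "\n")
  invisible(x)
}

#' Counterfactual classification with one code removed
#'
#' Recombines the profile after dropping the named code, quantifying that
#' code's contribution to the final classification (e.g. what the tier
#' would be without the functional-assay evidence). Removing an absent
#' code is a no-op.
#'
#' @param profile an [evidence_profile()].
#' @param code evidence code to drop, e.g. `"PS3"`; may be a vector.
#' @return an `"acmg_classification"` for the reduced profile.
#' @export
ablate <- function(profile, code) {
  stopifnot(inherits(profile, "evidence_profile"))
  keep <- !profile_codes(profile) %in% code
  combine_evidence(evidence_profile(items = profile$items[keep]))
}
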