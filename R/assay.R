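# Enzyme-activity measurement types and arithmetic.
#
# Residual activity is always expressed as % of the wild-type expression
# construct measured in the same assay run (raw units: nM 4MU/hour/mg
# protein). "Not detectable" is carried as a below-detection flag and
# compared as 0% against thresholds.

#' Validate a cDNA HGVS name against a minimal grammar
#'
#' Accepts the coding-sequence forms that occur in curated GAA tables:
#' substitutions (\code{c.316C>T}), deletions (\code{c.525delT},
#' \code{c.1589del}), duplications and insertions, and intronic-offset
#' positions (\code{c.-32-13T>G}). This is a sanity gate for curation
#' tables, not a full HGVS parser.
#'
#' @param cdna character vector of HGVS c. strings.
#' @return logical vector, `TRUE` where the string matches the grammar.
#' @examples
#' is_valid_cdna(c("c.316C>T", "c.-32-13T>G", "c.1589del", "p.Arg106Cys"))
#' @export
is_valid_cdna <- function(cdna) {
  pos <- "-?\\*?[0-9]+([+-][0-9]+)?"
  range <- paste0(pos, "(_", pos, ")?")
  change <- "([ACGT]+>[ACGT]+|del[ACGT]*|dup[ACGT]*|ins[ACGT]+|delins[ACGT]+)"
  re <- paste0("^c\\.", range, change, "$")
  !is.na(cdna) & nzchar(cdna) & grepl(re, cdna)
}

#' Variant identifier
#'
#' A variant is named by its cDNA HGVS string on a reference transcript,
#' optionally with a protein-level name.
#'
#' @param cdna HGVS c. string, e.g. \code{"c.316C>T"}. Required, and must
#'   match the minimal grammar checked by [is_valid_cdna()].
#' @param protein HGVS p. string, e.g. \code{"p.Arg106Cys"}, or `""`.
#' @param transcript reference transcript (default the MANE GAA transcript).
#' @return an object of class `"variant_id"`.
#' @export
variant_id <- function(cdna, protein = "", transcript = "NM_000152.5") {
  if (length(cdna) != 1L || is.na(cdna) || !nzchar(cdna)) {
    stop("'cdna' must be a single non-empty HGVS c. string", call. = FALSE)
  }
  if (!is_valid_cdna(cdna)) {
    stop(sprintf("'%s' does not match the supported HGVS c. grammar", cdna),
         call. = FALSE)
  }
  structure(
    list(cdna = cdna, protein = if (is.na(protein)) "" else protein,
         transcript = transcript),
    class = "variant_id"
  )
}

#' @export
format.variant_id <- function(x, ...) {
  if (nzchar(x$protein)) paste0(x$cdna, " (", x$protein, ")") else x$cdna
}

#' @export
print.variant_id <- function(x, ...) {
  cat(x$transcript, ":", format(x), "\n", sep = "")
  invisible(x)
}

#' Activity measurement for one variant construct
#'
#' Holds replicate activities (already normalized to % wild type, or raw --
#' normalization happens upstream via [percent_of_wildtype()]), a
#' below-detection flag, and the derived per-variant summary. The unrounded
#' replicate mean is kept for all threshold comparisons; the value rounded
#' to one decimal is for display only.
#'
#' @param replicates numeric vector of non-negative % wild-type values
#'   (length 0 allowed when `percent_wt` or `below_detection` is given).
#' @param percent_wt a single % wild-type value, used when replicates are
#'   not available. Ignored if `replicates` is non-empty.
#' @param below_detection logical; `TRUE` when no activity was detectable.
#'   Such measurements compare as 0% against any threshold.
#' @return an object of class `"activity_measurement"` with elements
#'   `replicates`, `below_detection`, `percent_wt` (unrounded) and
#'   `percent_display` (one decimal, half away from zero).
#' @examples
#' activity_measurement(c(11.05, 10.35))   # Arg106Cys replicate pair
#' activity_measurement(below_detection = TRUE)
#' @export
activity_measurement <- function(replicates = numeric(0), percent_wt = NULL,
                                 below_detection = FALSE) {
  replicates <- as.numeric(replicates[!is.na(replicates)])
  stopifnot(is.logical(below_detection), length(below_detection) == 1L)
  if (any(replicates < 0)) {
    stop("replicate activities must be non-negative", call. = FALSE)
  }
  if (below_detection) {
    pct <- NA_real_
  } else if (length(replicates) > 0L) {
    if (length(replicates) == 1L) {
      warning("single replicate: no within-assay reproducibility check",
              call. = FALSE)
    }
    pct <- mean(replicates)
  } else if (!is.null(percent_wt) && !is.na(percent_wt)) {
    if (percent_wt < 0) stop("percent_wt must be non-negative", call. = FALSE)
    pct <- as.numeric(percent_wt)
  } else {
    stop("missing activity data: give replicates, percent_wt, or below_detection = TRUE",
         call. = FALSE)
  }
  structure(
    list(replicates = replicates, below_detection = below_detection,
         percent_wt = pct,
         percent_display = if (is.na(pct)) NA_real_ else round_half_away(pct, 1L)),
    class = "activity_measurement"
  )
}

#' @export
print.activity_measurement <- function(x, ...) {
  if (x$below_detection) {
    cat("Activity: not detectable (compared as 0% of wild type)\n")
  } else {
    cat(sprintf("Activity: %.1f%% of wild type", x$percent_display))
    if (length(x$replicates) > 1L) {
      cat(" (replicates: ", paste(x$replicates, collapse = ", "), ")", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

# Effective value used in every threshold comparison.
effective_percent <- function(m) {
  if (inherits(m, "activity_measurement")) {
    if (m$below_detection) 0 else m$percent_wt
  } else {
    as.numeric(m)
  }
}

#' Normalize a raw activity to % of wild type
#'
#' Background (mock-transfection) activity is subtracted from both the
#' variant and the wild-type construct, with clipping at zero; when the mock
#' activity is 0 this reduces to the plain ratio.
#'
#' @param variant_raw raw activity of the variant construct (nM/hour/mg).
#' @param wildtype_raw raw activity of the wild-type positive control.
#' @param mock_raw raw activity of the mock-transfection negative control.
#' @return % of wild-type activity, never negative. Vectorized over
#'   `variant_raw`.
#' @examples
#' percent_of_wildtype(50, 1000, 0)    # 5
#' percent_of_wildtype(3, 1000, 5)     # sub-background, clipped to 0
#' @export
percent_of_wildtype <- function(variant_raw, wildtype_raw, mock_raw = 0) {
  stopifnot(length(wildtype_raw) == 1L, length(mock_raw) == 1L)
  if (is.na(wildtype_raw) || is.na(mock_raw) || wildtype_raw <= mock_raw) {
    stop("invalid assay run: wild-type activity must exceed mock background",
         call. = FALSE)
  }
  if (any(variant_raw < 0, na.rm = TRUE)) {
    stop("variant_raw must be non-negative", call. = FALSE)
  }
  100 * pmax(variant_raw - mock_raw, 0) / (wildtype_raw - mock_raw)
}

#' Average replicate % wild-type values
#'
#' Returns the arithmetic mean rounded to one decimal (half away from zero),
#' the convention used for reported activity values. The unrounded mean --
#' what threshold comparisons must use -- is available as attribute
#' `"unrounded"` or from [activity_measurement()].
#'
#' @param values numeric vector of % wild-type values, length >= 1.
#' @return the reported (1-decimal) mean with attribute `"unrounded"`.
#' @examples
#' average_replicates(c(11.05, 10.35))  # 10.7
#' average_replicates(c(1.8, 1.2))      # 1.5
#' @export
average_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("missing replicate data", call. = FALSE)
  }
  if (any(values < 0)) stop("replicate values must be non-negative", call. = FALSE)
  m <- mean(values)
  structure(round_half_away(m, 1L), unrounded = m)
}

# round half away from zero (base round() is round-half-even)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assemble an assay run from raw activities
#'
#' An assay run pairs the wild-type positive control and mock negative
#' control with raw per-variant replicate activities, and normalizes each
#' variant to % wild type via [percent_of_wildtype()].
#'
#' @param wildtype_activity raw activity of the wild-type construct.
#' @param mock_activity raw activity of the mock transfection.
#' @param measurements named list: variant cDNA -> numeric vector of raw
#'   replicate activities (or an [activity_measurement()] already in %).
#' @return an object of class `"assay_run"` whose `measurements` element is
#'   a named list of [activity_measurement()] objects in % wild type.
#' @export
assay_run <- function(wildtype_activity, mock_activity = 0, measurements = list()) {
  if (mock_activity < 0) stop("mock_activity must be non-negative", call. = FALSE)
  if (wildtype_activity <= mock_activity) {
    stop("invalid assay run: wild-type activity must exceed mock background",
         call. = FALSE)
  }
  if (length(measurements) && is.null(names(measurements))) {
    stop("measurements must be named by variant cDNA", call. = FALSE)
  }
  if (anyDuplicated(names(measurements))) {
    stop("variant ids must be unique within an assay run", call. = FALSE)
  }
  meas <- lapply(measurements, function(v) {
    if (inherits(v, "activity_measurement")) return(v)
    activity_measurement(
      replicates = percent_of_wildtype(v, wildtype_activity, mock_activity)
    )
  })
  structure(
    list(wildtype_activity = wildtype_activity, mock_activity = mock_activity,
         measurements = meas),
    class = "assay_run"
  )
}

#' @export
print.assay_run <- function(x, ...) {
  cat("GAA expression assay run\n")
  cat(sprintf("  wild-type control: %g, mock background: %g (raw units)\n",
              x$wildtype_activity, x$mock_activity))
  for (nm in names(x$measurements)) {
    m <- x$measurements[[nm]]
    val <- if (m$below_detection) "not detectable"
           else sprintf("%.1f%% WT", m$percent_display)
    cat(sprintf("  %-16s %s\n", nm, val))
  }
  invisible(x)
}
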