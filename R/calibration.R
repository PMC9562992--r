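# Calibration of the expression assay against control variants of known
# classification, following ClinGen SVI guidance for PS3/BS3 functional
# evidence: the pathogenic activity zone runs up to the highest activity
# seen in a pathogenic control, the benign zone starts at the lowest
# activity seen in a benign control, and the interval between them is
# indeterminate -- no functional evidence code may be applied there.

PATHOGENIC_CLASSES <- c("pathogenic", "likely_pathogenic")
BENIGN_CLASSES     <- c("benign", "likely_benign")
CONTROL_CLASSES    <- c(PATHOGENIC_CLASSES, BENIGN_CLASSES, "pseudodeficiency")

normalize_class <- function(x) {
  y <- gsub("[ /-]+", "_", tolower(trimws(x)))
  bad <- !y %in% CONTROL_CLASSES
  if (any(bad)) {
    stop(sprintf("unknown control classification '%s' (expected one of: %s)",
                 x[bad][1], paste(CONTROL_CLASSES, collapse = ", ")),
         call. = FALSE)
  }
  y
}

# per-row activity from a controls/observations data.frame:
# below_detection -> 0; else replicate mean (unrounded); else percent_wt
row_activity <- function(df) {
  rc <- rep_cols(df)
  vapply(seq_len(nrow(df)), function(i) {
    if (isTRUE(df$below_detection[i])) return(0)
    reps <- if (length(rc)) as.numeric(df[i, rc]) else numeric(0)
    reps <- reps[!is.na(reps)]
    if (length(reps)) return(mean(reps))
    if ("percent_wt" %in% names(df) && !is.na(df$percent_wt[i])) {
      return(as.numeric(df$percent_wt[i]))
    }
    stop(sprintf("control '%s': no activity data (replicates, percent_wt or below_detection)",
                 df$variant_cdna[i]), call. = FALSE)
  }, numeric(1))
}

#' Calibrate the functional assay from a control panel
#'
#' Fits the activity-zone model used to apply PS3/BS3 functional evidence:
#' the upper bound of the pathogenic zone is the maximum residual activity
#' among pathogenic / likely-pathogenic controls (below-detection counted
#' as 0%), and the lower bound of the benign zone is the minimum activity
#' among benign / likely-benign controls. A pseudodeficiency control, if
#' present, acts only as a sentinel: its activity must fall strictly
#' between the two bounds, otherwise a validation warning is recorded on
#' the fit. The evidence strength at which PS3/BS3 may be applied is set
#' from the control counts (see [determine_strength()]).
#'
#' @param controls a data.frame with columns `variant_cdna`, `known_class`
#'   and activity data (`percent_wt` or `rep1, rep2, ...` plus
#'   `below_detection`), e.g. from [read_controls_tsv()] or
#'   [gaa_control_panel()]. At least one pathogenic and one benign control
#'   are required.
#' @param policy control-count policy for PS3/BS3 strength:
#'   `"conservative"` (default) always applies the supporting level;
#'   `"svi"` grants the moderate level when a balanced panel of at least 11
#'   pathogenic-plus-benign controls was used.
#' @return an object of class `"activity_calibration"`: a list with
#'   elements `pathogenic_max`, `benign_min`, `n_pathogenic_controls`,
#'   `n_benign_controls`, `ps3_strength`, `bs3_strength`,
#'   `ps3_applicable`, `bs3_applicable`, `policy`, `warnings` and the
#'   echoed `controls` table (with the computed per-control activity).
#'   An overlapping panel (a benign control at or below a pathogenic
#'   control) is not a validatable assay and raises an error.
#' @examples
#' cal <- activity_calibration(gaa_control_panel())
#' cal
#' coef(cal)
#' predict(cal, c(2.8, 17, 80))
#' @seealso [classify_activity()], [determine_strength()],
#'   [simulate.activity_calibration()]
#' @export
activity_calibration <- function(controls, policy = c("conservative", "svi")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(controls))
  if (!all(c("variant_cdna", "known_class") %in% names(controls))) {
    stop("controls need 'variant_cdna' and 'known_class' columns", call. = FALSE)
  }
  if (anyNA(controls$known_class)) {
    stop("incomplete panel: every control needs a known classification",
         call. = FALSE)
  }
  if (anyDuplicated(controls$variant_cdna)) {
    stop("control variant ids must be unique", call. = FALSE)
  }
  if (!"below_detection" %in% names(controls)) controls$below_detection <- FALSE
  cls <- normalize_class(controls$known_class)
  act <- row_activity(controls)

  is_path <- cls %in% PATHOGENIC_CLASSES
  is_ben  <- cls %in% BENIGN_CLASSES
  is_pd   <- cls == "pseudodeficiency"
  n_path <- sum(is_path)
  n_ben  <- sum(is_ben)
  if (n_path < 1L || n_ben < 1L) {
    stop("incomplete panel: need at least one pathogenic and one benign/likely-benign control",
         call. = FALSE)
  }

  pathogenic_max <- max(act[is_path])
  benign_min     <- min(act[is_ben])
  if (benign_min <= pathogenic_max) {
    stop(sprintf(paste0("assay not validatable: benign control activity (%g%%) ",
                        "does not exceed pathogenic control activity (%g%%)"),
                 benign_min, pathogenic_max), call. = FALSE)
  }

  warnings <- character(0)
  if (any(is_pd)) {
    bad <- is_pd & !(act > pathogenic_max & act < benign_min)
    if (any(bad)) {
      warnings <- sprintf(paste0("pseudodeficiency control '%s' (%g%%) is not ",
                                 "strictly between the pathogenic (%g%%) and ",
                                 "benign (%g%%) bounds"),
                          controls$variant_cdna[bad], act[bad],
                          pathogenic_max, benign_min)
      for (w in warnings) warning(w, call. = FALSE)
    }
  }

  strength <- determine_strength(n_path, n_ben, policy)
  echoed <- data.frame(
    variant_cdna = controls$variant_cdna,
    variant_protein = if ("variant_protein" %in% names(controls))
      controls$variant_protein else "",
    known_class = cls,
    activity = act,
    below_detection = as.logical(controls$below_detection),
    stringsAsFactors = FALSE
  )

  structure(
    list(pathogenic_max = pathogenic_max, benign_min = benign_min,
         n_pathogenic_controls = n_path, n_benign_controls = n_ben,
         ps3_strength = strength$ps3, bs3_strength = strength$bs3,
         ps3_applicable = n_path >= 1L, bs3_applicable = n_ben >= 1L,
         policy = policy, warnings = warnings, controls = echoed,
         call = match.call()),
    class = "activity_calibration"
  )
}

#' PS3/BS3 evidence strength from control counts
#'
#' Under the `"svi"` policy the moderate level requires a balanced mix of
#' at least 11 validated controls (both classes represented); otherwise,
#' and always under the `"conservative"` policy, functional evidence is
#' applied at the supporting level.
#'
#' @param n_pathogenic,n_benign numbers of pathogenic and benign/likely-
#'   benign controls used to validate the assay.
#' @param policy `"conservative"` or `"svi"`.
#' @param min_total minimum total control count for the moderate level
#'   under `"svi"` (default 11).
#' @param min_each minimum per-class count for "balanced" (default 1).
#' @return list with elements `ps3` and `bs3`, each `"supporting"` or
#'   `"moderate"`.
#' @export
determine_strength <- function(n_pathogenic, n_benign,
                               policy = c("conservative", "svi"),
                               min_total = 11L, min_each = 1L) {
  policy <- match.arg(policy)
  stopifnot(n_pathogenic >= 0, n_benign >= 0)
  level <- if (policy == "svi" &&
               n_pathogenic + n_benign >= min_total &&
               n_pathogenic >= min_each && n_benign >= min_each) {
    "moderate"
  } else {
    "supporting"
  }
  list(ps3 = level, bs3 = level)
}

#' Place an activity value in the calibrated zones
#'
#' Activities strictly below the pathogenic bound fall in the pathogenic
#' range; activities at or above the benign bound fall in the benign range;
#' everything between (both bounds included on the pathogenic side, i.e.
#' an activity exactly at the pathogenic bound) is indeterminate.
#' Below-detection measurements compare as 0% and always fall in the
#' pathogenic range.
#'
#' @param percent % wild-type activity (numeric vector), or an
#'   [activity_measurement()].
#' @param cal an [activity_calibration()] fit.
#' @param below_detection logical vector (recycled) marking not-detectable
#'   measurements; ignored when `percent` is an [activity_measurement()].
#' @return factor with levels `pathogenic_range`, `indeterminate`,
#'   `benign_range`.
#' @examples
#' cal <- activity_calibration(gaa_control_panel())
#' classify_activity(c(2.8, 11, 17.5, 54, 80), cal)
#' @export
classify_activity <- function(percent, cal, below_detection = FALSE) {
  stopifnot(inherits(cal, "activity_calibration"))
  if (inherits(percent, "activity_measurement")) {
    below_detection <- percent$below_detection
    percent <- if (percent$below_detection) 0 else percent$percent_wt
  }
  below_detection <- rep_len(as.logical(below_detection), length(percent))
  percent <- ifelse(below_detection, 0, as.numeric(percent))
  zone <- ifelse(below_detection | percent < cal$pathogenic_max, "pathogenic_range",
          ifelse(percent >= cal$benign_min, "benign_range", "indeterminate"))
  factor(zone, levels = c("pathogenic_range", "indeterminate", "benign_range"))
}

#' @export
print.activity_calibration <- function(x, ...) {
  cat("Functional assay calibration (GAA residual activity, % wild type)\n")
  cat(sprintf("  pathogenic zone:    < %g%%   (%d pathogenic controls)\n",
              x$pathogenic_max, x$n_pathogenic_controls))
  cat(sprintf("  indeterminate zone: [%g%%, %g%%)\n",
              x$pathogenic_max, x$benign_min))
  cat(sprintf("  benign zone:        >= %g%%  (%d benign controls)\n",
              x$benign_min, x$n_benign_controls))
  cat(sprintf("  policy: %s -> PS3_%s / BS3_%s\n",
              x$policy, x$ps3_strength, x$bs3_strength))
  if (length(x$warnings)) {
    cat("  validation warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' @export
summary.activity_calibration <- function(object, ...) {
  structure(object, class = c("summary.activity_calibration",
                              class(object)))
}

#' @export
print.summary.activity_calibration <- function(x, ...) {
  NextMethod()
  cat("\nControl panel:\n")
  df <- x$controls
  df$activity <- ifelse(df$below_detection, "ND (0)",
                        formatC(df$activity, format = "g"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.activity_calibration <- function(object, ...) {
  c(pathogenic_max = object$pathogenic_max, benign_min = object$benign_min)
}

#' Classify new activities against a calibration
#'
#' @param object an [activity_calibration()] fit.
#' @param newdata numeric vector of % wild-type activities, or a data.frame
#'   with `percent_wt`/replicate columns and `below_detection`. Defaults to
#'   the fitted control activities.
#' @param type `"zone"` returns the activity-zone factor;
#'   `"evidence"` returns the applicable functional-evidence code
#'   (`"PS3_<strength>"`, `"BS3_<strength>"`, or `NA` in the
#'   indeterminate zone).
#' @param ... unused.
#' @return factor (zones) or character vector (evidence codes).
#' @export
predict.activity_calibration <- function(object, newdata = NULL,
                                         type = c("zone", "evidence"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    pct <- object$controls$activity
    bd <- object$controls$below_detection
  } else if (is.data.frame(newdata)) {
    if (!"below_detection" %in% names(newdata)) newdata$below_detection <- FALSE
    pct <- row_activity(newdata)
    bd <- as.logical(newdata$below_detection)
  } else {
    pct <- as.numeric(newdata)
    bd <- FALSE
  }
  zone <- classify_activity(pct, object, bd)
  if (type == "zone") return(zone)
  ifelse(zone == "pathogenic_range", paste0("PS3_", object$ps3_strength),
  ifelse(zone == "benign_range", paste0("BS3_", object$bs3_strength),
         NA_character_))
}

#' Plot a calibration: control activities and zone boundaries
#'
#' Strip chart of control residual activities by class, with the pathogenic
#' and benign zone boundaries drawn as horizontal lines and the
#' indeterminate zone shaded.
#'
#' @param x an [activity_calibration()] fit.
#' @param ... passed to [graphics::stripchart()].
#' @return `x`, invisibly.
#' @export
plot.activity_calibration <- function(x, ...) {
  df <- x$controls
  grp <- factor(ifelse(df$known_class %in% PATHOGENIC_CLASSES, "pathogenic",
                ifelse(df$known_class %in% BENIGN_CLASSES, "benign",
                       "pseudodeficiency")),
                levels = c("pathogenic", "pseudodeficiency", "benign"))
  graphics::stripchart(df$activity ~ grp, vertical = TRUE, pch = 19,
                       method = "jitter", jitter = 0.08,
                       ylab = "residual activity (% wild type)",
                       ylim = c(0, max(100, df$activity)), ...)
  graphics::rect(0.5, x$pathogenic_max, 3.5, x$benign_min,
                 col = grDevices::adjustcolor("grey", 0.3), border = NA)
  graphics::abline(h = c(x$pathogenic_max, x$benign_min), lty = 2)
  graphics::text(3.4, x$pathogenic_max, sprintf("%g%%", x$pathogenic_max),
                 pos = 3, cex = 0.8)
  graphics::text(3.4, x$benign_min, sprintf("%g%%", x$benign_min),
                 pos = 1, cex = 0.8)
  invisible(x)
}

#' Simulate control panels from a fitted calibration
#'
#' Draws synthetic control panels whose true zone boundaries are the fitted
#' ones, using the generator from [generate_panel()]. Useful for assessing
#' how tightly a panel of this size pins down the thresholds.
#'
#' @param object an [activity_calibration()] fit.
#' @param nsim number of panels.
#' @param seed integer seed (the global RNG state is restored on exit).
#' @param replicate_sd,n_replicates noise scale (% points) and replicate
#'   count per synthetic control.
#' @param ... unused.
#' @return a list of `nsim` control data.frames.
#' @export
simulate.activity_calibration <- function(object, nsim = 1, seed = NULL,
                                          replicate_sd = 1, n_replicates = 2,
                                          ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  lapply(seq_len(nsim), function(i) {
    generate_panel(panel_spec(
      n_pathogenic = object$n_pathogenic_controls,
      n_benign = object$n_benign_controls,
      include_pseudodeficiency = any(object$controls$known_class == "pseudodeficiency"),
      true_pathogenic_max = object$pathogenic_max,
      true_benign_min = object$benign_min,
      replicate_sd = replicate_sd, n_replicates = n_replicates,
      seed = seed + i - 1L
    ))
  })
}
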