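# Readers and writers for the plain-text table dialects used throughout:
# tab-separated, one header line, UTF-8, "." decimal separator, "NA" for
# missing, no quoting (HGVS strings contain no tabs). Numbers are written
# with 17 significant digits so a write/read round trip is bit-identical.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: '%s'", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE, quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: '%s' (line 1) is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

check_numeric_col <- function(df, col, path) {
  if (!col %in% names(df)) return(df)
  v <- df[[col]]
  if (is.numeric(v) || all(is.na(v))) {
    df[[col]] <- as.numeric(v)
    return(df)
  }
  coerced <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(coerced))
  if (length(bad)) {
    stop(sprintf("'%s' line %d, column '%s': cannot parse '%s' as a number",
                 path, bad[1] + 1L, col, v[bad[1]]), call. = FALSE)
  }
  df[[col]] <- coerced
  df
}

check_logical_col <- function(df, col, path) {
  if (!col %in% names(df)) return(df)
  v <- df[[col]]
  if (is.logical(v)) return(df)
  lv <- tolower(as.character(v))
  out <- ifelse(lv %in% c("true", "t", "1"), TRUE,
                ifelse(lv %in% c("false", "f", "0"), FALSE, NA))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad)) {
    stop(sprintf("'%s' line %d, column '%s': cannot parse '%s' as true/false",
                 path, bad[1] + 1L, col, v[bad[1]]), call. = FALSE)
  }
  df[[col]] <- out
  df
}

rep_cols <- function(df) grep("^rep[0-9]+$", names(df), value = TRUE)
af_cols  <- function(df) grep("^af_", names(df), value = TRUE)

#' Read a control-panel table
#'
#' Expected columns: `variant_cdna`, `variant_protein`, `known_class`
#' (pathogenic / likely_pathogenic / benign / likely_benign /
#' pseudodeficiency), and either `percent_wt` or replicate columns
#' `rep1, rep2, ...`, plus `below_detection` (true/false).
#'
#' @param path path to a tab-separated file.
#' @return a data.frame, one row per control variant.
#' @seealso [activity_calibration()], [write_controls_tsv()]
#' @export
read_controls_tsv <- function(path) {
  df <- read_tsv_checked(path, c("variant_cdna", "known_class"), "controls")
  for (col in c("percent_wt", rep_cols(df))) df <- check_numeric_col(df, col, path)
  df <- check_logical_col(df, "below_detection", path)
  if (!"below_detection" %in% names(df)) df$below_detection <- FALSE
  df$below_detection[is.na(df$below_detection)] <- FALSE
  if (anyDuplicated(df$variant_cdna)) {
    stop(sprintf("'%s': duplicate variant id '%s'", path,
                 df$variant_cdna[duplicated(df$variant_cdna)][1]), call. = FALSE)
  }
  df
}

#' Write a control-panel table
#'
#' @param controls a data.frame as returned by [read_controls_tsv()] or
#'   [gaa_control_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_controls_tsv <- function(controls, path) {
  write_tsv_plain(controls, path)
}

#' Read a variant-observations table
#'
#' One row per tested variant. Activity is given as replicate columns
#' `rep1, rep2, ...` or a `percent_wt` column, with `below_detection`.
#' Population allele frequencies come in any number of `af_<population>`
#' columns (all-`NA` meaning absent from population databases). Remaining
#' columns: `in_trans_pathogenic`, `trans_partner`, `same_codon_pathogenic`,
#' `same_codon_variant`, `revel`, `phenotype_consistent`,
#' `pseudodeficiency_excluded`, `protein_bands`.
#'
#' @param path path to a tab-separated file.
#' @return a data.frame, one row per tested variant.
#' @export
read_observations_tsv <- function(path) {
  df <- read_tsv_checked(path, "variant_cdna", "observations")
  for (col in c("percent_wt", "revel", rep_cols(df), af_cols(df))) {
    df <- check_numeric_col(df, col, path)
  }
  for (col in c("below_detection", "in_trans_pathogenic",
                "same_codon_pathogenic", "phenotype_consistent",
                "pseudodeficiency_excluded")) {
    df <- check_logical_col(df, col, path)
    if (!col %in% names(df)) df[[col]] <- FALSE
    df[[col]][is.na(df[[col]])] <- FALSE
  }
  if (anyDuplicated(df$variant_cdna)) {
    stop(sprintf("'%s': duplicate variant id '%s'", path,
                 df$variant_cdna[duplicated(df$variant_cdna)][1]), call. = FALSE)
  }
  df
}

#' Write a variant-observations table
#'
#' @param observations a data.frame as returned by [read_observations_tsv()]
#'   or [gaa_variant_observations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations_tsv <- function(observations, path) {
  write_tsv_plain(observations, path)
}

# shared TSV writer: full numeric precision, "NA" for missing, no quoting
write_tsv_plain <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
    if (is.logical(out[[col]])) out[[col]] <- tolower(as.character(out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an assay run as a TSV of % wild-type replicates
#'
#' Each measurement is written normalized to % wild type (`units` column =
#' `"percent"`); re-reading with [read_assay_tsv()] reproduces every
#' `percent_wt` bit-identically.
#'
#' @param run an [assay_run()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assay_tsv <- function(run, path) {
  stopifnot(inherits(run, "assay_run"))
  meas <- run$measurements
  nrep <- max(c(1L, vapply(meas, function(m) length(m$replicates), integer(1))))
  rows <- lapply(names(meas), function(nm) {
    m <- meas[[nm]]
    reps <- c(m$replicates, rep(NA_real_, nrep - length(m$replicates)))
    c(variant_cdna = nm, units = "percent",
      stats::setNames(fmt_num(reps), paste0("rep", seq_len(nrep))),
      below_detection = tolower(as.character(m$below_detection)))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an assay TSV back into an assay run
#'
#' Accepts the dialect written by [write_assay_tsv()]: a `units` column
#' declaring `"percent"` or `"raw"`; raw tables must contain reserved rows
#' `wildtype` and `mock` used to normalize the remaining rows.
#'
#' @param path path to a tab-separated file.
#' @return an [assay_run()] with measurements in % wild type.
#' @export
read_assay_tsv <- function(path) {
  df <- read_tsv_checked(path, c("variant_cdna", "units"), "assay")
  for (col in rep_cols(df)) df <- check_numeric_col(df, col, path)
  df <- check_logical_col(df, "below_detection", path)
  if (!"below_detection" %in% names(df)) df$below_detection <- FALSE
  df$below_detection[is.na(df$below_detection)] <- FALSE
  rc <- rep_cols(df)
  raw <- any(df$units == "raw")
  wt <- 100; mock <- 0
  if (raw) {
    iw <- match("wildtype", df$variant_cdna)
    im <- match("mock", df$variant_cdna)
    if (is.na(iw)) stop(sprintf("'%s': raw units require a 'wildtype' row", path),
                        call. = FALSE)
    wt <- mean(as.numeric(df[iw, rc]), na.rm = TRUE)
    mock <- if (is.na(im)) 0 else mean(as.numeric(df[im, rc]), na.rm = TRUE)
    df <- df[-stats::na.omit(c(iw, im)), , drop = FALSE]
  }
  meas <- lapply(seq_len(nrow(df)), function(i) {
    reps <- as.numeric(df[i, rc])
    reps <- reps[!is.na(reps)]
    if (df$below_detection[i]) return(activity_measurement(below_detection = TRUE))
    if (df$units[i] == "raw") reps <- percent_of_wildtype(reps, wt, mock)
    activity_measurement(replicates = reps)
  })
  names(meas) <- df$variant_cdna
  structure(
    list(wildtype_activity = wt, mock_activity = mock, measurements = meas),
    class = "assay_run"
  )
}

#' Read or write a VCEP threshold profile as JSON
#'
#' @param path path to a JSON file with the [vcep_profile()] fields.
#' @return for `read_vcep_profile()`, a [vcep_profile()]; for
#'   `write_vcep_profile()`, `path` invisibly.
#' @export
read_vcep_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(vcep_profile, x[intersect(names(x), names(formals(vcep_profile)))])
}

#' @rdname read_vcep_profile
#' @param profile a [vcep_profile()].
#' @export
write_vcep_profile <- function(profile, path) {
  stopifnot(inherits(profile, "vcep_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a calibration result as an audit JSON document
#'
#' Emits every calibration field plus the echoed control list, so the
#' provenance of the activity thresholds can be reviewed alongside any
#' classification that used them.
#'
#' @param cal an [activity_calibration()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "activity_calibration"))
  doc <- list(
    pathogenic_max = cal$pathogenic_max,
    benign_min = cal$benign_min,
    n_pathogenic_controls = cal$n_pathogenic_controls,
    n_benign_controls = cal$n_benign_controls,
    ps3_strength = cal$ps3_strength,
    bs3_strength = cal$bs3_strength,
    ps3_applicable = cal$ps3_applicable,
    bs3_applicable = cal$bs3_applicable,
    policy = cal$policy,
    warnings = cal$warnings,
    controls = cal$controls
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
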