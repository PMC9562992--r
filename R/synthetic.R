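# Seeded synthetic-data generators. These emulate the statistical
# structure the analysis assumes -- control activities drawn from
# separated zones with additive replicate noise, and evidence observations
# spanning the PM2/none/BS1, BP4/none/PP3 and zone strata -- so every
# pipeline stage is testable without any external data.

# evaluate expr under a fixed RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic control panel
#'
#' Defaults mirror the structure of the real validation panel: 7
#' pathogenic and 4 benign controls plus one pseudodeficiency sentinel,
#' true zone boundaries at 11% and 54%, two replicates per control, and a
#' replicate noise scale of 1 percentage point (the order of magnitude of
#' the observed replicate spread, which was at most ~1.7 points).
#'
#' @param n_pathogenic,n_benign control counts per class.
#' @param include_pseudodeficiency draw one pseudodeficiency control
#'   strictly inside the gap?
#' @param true_pathogenic_max,true_benign_min true zone boundaries (% WT).
#' @param replicate_sd additive Gaussian replicate noise (percentage
#'   points), clipped at 0.
#' @param n_replicates replicates per control.
#' @param seed integer seed.
#' @return an object of class `"panel_spec"`.
#' @export
panel_spec <- function(n_pathogenic = 7L, n_benign = 4L,
                       include_pseudodeficiency = TRUE,
                       true_pathogenic_max = 11, true_benign_min = 54,
                       replicate_sd = 1, n_replicates = 2L, seed = 1L) {
  stopifnot(n_pathogenic >= 0, n_benign >= 0, replicate_sd >= 0,
            n_replicates >= 1)
  if (!(true_pathogenic_max >= 0 && true_pathogenic_max < true_benign_min &&
        true_benign_min <= 100)) {
    stop("need 0 <= true_pathogenic_max < true_benign_min <= 100",
         call. = FALSE)
  }
  if (include_pseudodeficiency &&
      true_benign_min - true_pathogenic_max <= .Machine$double.eps * 100) {
    stop("pseudodeficiency control requested but there is no gap between the zones",
         call. = FALSE)
  }
  structure(
    list(n_pathogenic = as.integer(n_pathogenic),
         n_benign = as.integer(n_benign),
         include_pseudodeficiency = isTRUE(include_pseudodeficiency),
         true_pathogenic_max = true_pathogenic_max,
         true_benign_min = true_benign_min,
         replicate_sd = replicate_sd,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' Generate a synthetic control panel
#'
#' True per-control activities are drawn uniformly within each zone
#' (pathogenic on \[0, true_pathogenic_max\], benign on
#' \[true_benign_min, 100\], pseudodeficiency strictly between), then
#' expanded to replicates with additive zero-mean Gaussian noise clipped
#' at 0. Reproducible given the spec's seed; the global RNG state is
#' untouched.
#'
#' @param spec a [panel_spec()].
#' @return a data.frame in the controls-TSV layout, with replicate columns.
#' @examples
#' panel <- generate_panel(panel_spec(seed = 7, replicate_sd = 0))
#' coef(activity_calibration(panel))
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    truth <- c(
      stats::runif(spec$n_pathogenic, 0, spec$true_pathogenic_max),
      stats::runif(spec$n_benign, spec$true_benign_min, 100),
      if (spec$include_pseudodeficiency) {
        stats::runif(1, spec$true_pathogenic_max, spec$true_benign_min)
      }
    )
    cls <- c(rep("pathogenic", spec$n_pathogenic),
             rep("benign", spec$n_benign),
             if (spec$include_pseudodeficiency) "pseudodeficiency")
    n <- length(truth)
    reps <- matrix(pmax(0, rep(truth, each = spec$n_replicates) +
                          stats::rnorm(n * spec$n_replicates,
                                       sd = spec$replicate_sd)),
                   nrow = n, byrow = TRUE)
    colnames(reps) <- paste0("rep", seq_len(spec$n_replicates))
    out <- data.frame(
      variant_cdna = sprintf("c.%dA>G", seq_len(n) * 3L + 1L),
      variant_protein = "",
      known_class = cls,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(reps))
    out$below_detection <- FALSE
    out$true_activity <- truth
    out
  })
}

#' Generate synthetic variant observations
#'
#' Draws `n` observation rows whose activities, allele frequencies and
#' REVEL scores are stratified across the calibrated activity zones and
#' the PM2/none/BS1 and BP4/none/PP3 threshold strata, with random phase /
#' same-codon / phenotype booleans, so the full assigner-plus-engine path
#' can be fuzzed. The intended stratum labels are attached as attribute
#' `"strata"` for generator self-checks.
#'
#' @param n number of observations.
#' @param seed integer seed.
#' @param cal an [activity_calibration()] fit.
#' @param profile a [vcep_profile()].
#' @return a data.frame in the observations-TSV layout with attribute
#'   `"strata"`.
#' @export
generate_observations <- function(n, seed, cal = NULL,
                                  profile = vcep_profile()) {
  stopifnot(n >= 1)
  if (is.null(cal)) cal <- activity_calibration(gaa_control_panel())
  with_seed(seed, {
    zone <- sample(c("pathogenic_range", "indeterminate", "benign_range"),
                   n, replace = TRUE)
    eps <- 1e-6
    pct <- vapply(zone, function(z) switch(z,
      pathogenic_range = stats::runif(1, 0, cal$pathogenic_max * (1 - eps)),
      indeterminate = stats::runif(1, cal$pathogenic_max,
                                   cal$benign_min * (1 - eps)),
      benign_range = stats::runif(1, cal$benign_min, 100)), numeric(1))
    bd <- zone == "pathogenic_range" & stats::runif(n) < 0.25
    pct[bd] <- NA_real_

    af_stratum <- sample(c("pm2", "none", "bs1", "absent"), n, replace = TRUE)
    af <- vapply(af_stratum, function(s) switch(s,
      pm2 = stats::runif(1, 0, profile$pm2_af_max * (1 - eps)),
      none = stats::runif(1, profile$pm2_af_max, profile$bs1_af_min),
      bs1 = stats::runif(1, profile$bs1_af_min * (1 + eps),
                         min(1, profile$bs1_af_min * 10)),
      absent = NA_real_), numeric(1))

    revel_stratum <- sample(c("bp4", "none", "pp3", "missing"), n,
                            replace = TRUE)
    revel <- vapply(revel_stratum, function(s) switch(s,
      bp4 = stats::runif(1, 0, profile$bp4_revel_max * (1 - eps)),
      none = stats::runif(1, profile$bp4_revel_max, profile$pp3_revel_min),
      pp3 = stats::runif(1, profile$pp3_revel_min * (1 + eps), 1),
      missing = NA_real_), numeric(1))

    in_trans <- stats::runif(n) < 0.5
    same_codon <- stats::runif(n) < 0.2
    pheno <- stats::runif(n) < 0.7
    pd_excl <- stats::runif(n) < 0.9

    obs <- data.frame(
      variant_cdna = sprintf("c.%dC>T", seq_len(n) * 3L + 1L),
      variant_protein = "",
      percent_wt = pct,
      below_detection = bd,
      af_global = af,
      in_trans_pathogenic = in_trans,
      trans_partner = ifelse(in_trans, "c.-32-13T>G", ""),
      same_codon_pathogenic = same_codon,
      same_codon_variant = ifelse(same_codon, "c.1124G>T (p.Arg375Leu)", ""),
      revel = revel,
      phenotype_consistent = pheno,
      pseudodeficiency_excluded = pd_excl,
      protein_bands = sample(c("precursor_and_mature", "precursor_only",
                               "none_observed", "not_assayed"),
                             n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    attr(obs, "strata") <- data.frame(zone = zone, af = af_stratum,
                                      revel = revel_stratum,
                                      stringsAsFactors = FALSE)
    obs
  })
}

#' Write the packaged study tables as plain-text fixtures
#'
#' Emits the control panel, the replicate-activity table, the tested-
#' variant observation table, and the default VCEP profile into a
#' directory, in the TSV/JSON dialects read by the pipeline. Output is
#' byte-stable across runs.
#'
#' @param directory output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @examples
#' paths <- write_study_fixtures(tempfile("fixtures"))
#' basename(paths)
#' @export
write_study_fixtures <- function(directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    controls = file.path(directory, "control_panel.tsv"),
    replicates = file.path(directory, "assay_replicates.tsv"),
    observations = file.path(directory, "variant_observations.tsv"),
    profile = file.path(directory, "vcep_profile.json")
  )
  write_controls_tsv(gaa_control_panel(), paths[["controls"]])
  write_tsv_plain(gaa_assay_replicates(), paths[["replicates"]])
  write_observations_tsv(gaa_variant_observations(), paths[["observations"]])
  write_vcep_profile(vcep_profile(), paths[["profile"]])
  invisible(paths)
}
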