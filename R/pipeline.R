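#' Pipeline configuration
#'
#' One list holding every tunable of the end-to-end runs, with the module
#' defaults. Any field can be overridden; the configuration (and its short
#' hash) is serialized next to the outputs so a run is reproducible from
#' (config, seed) alone.
#'
#' @param n_per_group eyes per pooled severity group (cross-sectional run).
#' @param n_pairs number of longitudinal pairs (longitudinal run).
#' @param seed master seed.
#' @param outdir output directory, or NULL to skip writing files.
#' @param noise_level speckle contrast of generated scenes.
#' @param phansalkar \code{\link{phansalkar_params}} for vessel binarization.
#' @param min_object_px speck threshold in telangiectasia circumscription.
#' @param min_large_vessel_px,min_width_px SCP large-vessel component filter.
#' @param roi_dilate_px how far the emulated operator marking extends beyond
#'   the true telangiectasia footprint.
#' @param min_change_px speck filter for the EZ change maps.
#' @param pv_domain \code{"exclude_baseline_ez"} or \code{"full"}.
#' @param register \code{\link{register_config}} for the longitudinal run.
#' @param longitudinal \code{\link{longitudinal_params}} template (its seed
#'   is re-derived per pair).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_per_group = 10, n_pairs = 50, seed = 1,
                            outdir = NULL, noise_level = 0.1,
                            phansalkar = phansalkar_params(),
                            min_object_px = 10,
                            min_large_vessel_px = 300, min_width_px = 4,
                            roi_dilate_px = 2, min_change_px = 8,
                            pv_domain = c("exclude_baseline_ez", "full"),
                            register = register_config(),
                            longitudinal = longitudinal_params()) {
  structure(list(n_per_group = n_per_group, n_pairs = n_pairs, seed = seed,
                 outdir = outdir, noise_level = noise_level,
                 phansalkar = phansalkar, min_object_px = min_object_px,
                 min_large_vessel_px = min_large_vessel_px,
                 min_width_px = min_width_px, roi_dilate_px = roi_dilate_px,
                 min_change_px = min_change_px,
                 pv_domain = match.arg(pv_domain), register = register,
                 longitudinal = longitudinal),
            class = "pipeline_config")
}

.log_line <- function(log, fmt, ...) {
  line <- sprintf(fmt, ...)
  c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), line))
}

.write_outputs <- function(outdir, config, tables, log) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  cfg$outdir <- NULL          # hash the scientific config, not the file paths
  hash <- config_hash(cfg)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab)) next
    path <- file.path(outdir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# config_hash=%s", hash), con)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
  }
  jsonlite::write_json(c(list(config_hash = hash), unclass(config)),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  writeLines(c(sprintf("# config_hash=%s", hash), log),
             file.path(outdir, "run.log"))
  invisible(hash)
}

#' Segment one eye end to end
#'
#' The per-eye chain of the cross-sectional pipeline: Phansalkar
#' circumscription of the marked telangiectasia zone, large-vessel artifact
#' exclusion, nested-region decomposition, and the per-eye record of areas
#' and overlaps. Exposed separately so single scenes can be analyzed
#' interactively.
#'
#' @param scene an \code{octa_scene}.
#' @param meta one-row data.frame with patient_id, eye_id, laterality,
#'   stage.
#' @param config \code{\link{pipeline_config}}.
#' @param roi optional marked ROI; by default the operator marking is
#'   emulated by dilating the true telangiectasia footprint by
#'   \code{roi_dilate_px}.
#' @return one-row data.frame (see \code{\link{eye_record}}).
#' @export
analyze_eye <- function(scene, meta, config = pipeline_config(), roi = NULL) {
  truth <- scene$truth
  s <- scale_mm_per_px(scene$dcp)
  if (is.null(roi)) roi <- mask_dilate(truth$telangiectasia, config$roi_dilate_px)
  tel <- withCallingHandlers(
    circumscribe_telangiectasia(scene$dcp, roi, config$phansalkar,
                                config$min_object_px),
    warning = function(w) invokeRestart("muffleWarning"))
  scp_large <- scp_artifact_mask(scene$scp, config$min_large_vessel_px,
                                 config$min_width_px)
  tel <- exclude_artifacts(tel, scp_large, quiet = TRUE)
  regions <- decompose_regions(truth$region_combined_A, truth$region_combined_B,
                               truth$region_ez_C, scale_mm_per_px = s)
  suppressWarnings(
    eye_record(meta$patient_id, meta$eye_id, meta$laterality, meta$stage,
               tel, regions))
}

#' Run the cross-sectional pipeline on a synthetic cohort
#'
#' Generates a cohort (\code{n_per_group} eyes per pooled stage group),
#' runs the per-eye segmentation and region decomposition, assembles the
#' per-eye records and produces the cross-sectional report (stage
#' correlations and by-group GEE comparisons). Per-eye failures are logged
#' and skipped; the run errors out if more than 20 percent of eyes fail.
#' With an \code{outdir}, writes \code{cohort.csv}, \code{correlations.csv},
#' \code{by_group.csv}, \code{pairwise.csv}, \code{config.json} and
#' \code{run.log}, each table prefixed with the config hash.
#'
#' @param config \code{\link{pipeline_config}}.
#' @return list with \code{records}, \code{report}, \code{manifest},
#'   \code{log}, \code{config}.
#' @export
run_cross_sectional <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  coh <- generate_cohort(config$n_per_group, config$seed, config$noise_level)
  n_eyes <- nrow(coh$manifest)
  log <- .log_line(log, "cohort: %d eyes, seed %d", n_eyes, config$seed)
  recs <- vector("list", n_eyes)
  failed <- 0
  for (i in seq_len(n_eyes)) {
    meta <- coh$manifest[i, ]
    recs[[i]] <- tryCatch({
      scene <- generate_scene(coh$scene_params[[i]])
      analyze_eye(scene, meta, config)
    }, error = function(e) {
      log <<- .log_line(log, "eye %s FAILED: %s", meta$eye_id, conditionMessage(e))
      failed <<- failed + 1
      NULL
    })
  }
  if (failed > 0.2 * n_eyes)
    stop(sprintf("%d of %d eyes failed", failed, n_eyes))
  records <- do.call(rbind, recs)
  n_noperfusion <- sum(is.na(records$overlap_ezloss_pct))
  log <- .log_line(log, "%d eyes analyzed, %d failed, %d with undefined overlap",
                   nrow(records), failed, n_noperfusion)
  report <- cross_sectional_report(records)
  .write_outputs(config$outdir, config,
                 list(cohort = records, correlations = report$correlations,
                      by_group = report$by_group, pairwise = report$pairwise),
                 log)
  list(records = records, report = report, manifest = coh$manifest,
       log = log, config = config)
}

#' Run the longitudinal pipeline on synthetic baseline/follow-up pairs
#'
#' Generates \code{n_pairs} eyes in the follow-up regime
#' (\code{\link{longitudinal_scene_params}}), creates a warped follow-up
#' visit for each, and runs the full longitudinal chain per pair: SCP
#' registration, transfer of follow-up regions, EZ change maps, and
#' predictive values of baseline IZ loss for new EZ loss. Eyes whose
#' registration fails are flagged and excluded from the cohort means.
#'
#' @param config \code{\link{pipeline_config}}.
#' @return list with \code{per_eye} (one row per pair), \code{summary}
#'   (cohort mean and SD of PPV, NPV, rPPV, rNPV and the change areas),
#'   \code{log}, \code{config}.
#' @export
run_longitudinal <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * config$n_pairs),
                  ncol = 2)
  rows <- vector("list", config$n_pairs)
  for (i in seq_len(config$n_pairs)) {
    rows[[i]] <- tryCatch({
      sp <- longitudinal_scene_params(seed = seeds[i, 1],
                                      noise_level = config$noise_level)
      scene <- generate_scene(sp)
      lp <- config$longitudinal
      lp$seed <- seeds[i, 2]
      pair <- generate_longitudinal(scene, lp)
      row <- analyze_pair(pair, config$register, config$min_change_px,
                          config$pv_domain)
      row$eye <- i
      row
    }, error = function(e) {
      log <<- .log_line(log, "pair %d FAILED: %s", i, conditionMessage(e))
      NULL
    })
  }
  per_eye <- do.call(rbind, rows)
  if (is.null(per_eye)) stop("all longitudinal pairs failed")
  log <- .log_line(log, "%d of %d pairs analyzed; mean registration EPE %.3f px",
                   nrow(per_eye), config$n_pairs, mean(per_eye$reg_epe_px))
  vars <- c("ppv", "npv", "prevalence", "rppv", "rnpv",
            "new_ez_mm2", "recovery_mm2")
  summ <- data.frame(
    quantity = vars,
    mean = vapply(vars, function(v) mean(per_eye[[v]], na.rm = TRUE), 0),
    sd = vapply(vars, function(v) stats::sd(per_eye[[v]], na.rm = TRUE), 0),
    n = vapply(vars, function(v) sum(!is.na(per_eye[[v]])), 0))
  .write_outputs(config$outdir, config,
                 list(longitudinal_per_eye = per_eye,
                      longitudinal_summary = summ),
                 log)
  list(per_eye = per_eye, summary = summ, log = log, config = config)
}
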