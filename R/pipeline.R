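# End-to-end session pipeline: normalize -> register to the Doppler
# reference -> compose with the pre-aligned reference-to-atlas transform ->
# propagate labels, with provenance and a QC report.

#' Pipeline configuration
#'
#' Validates paths eagerly so misconfiguration fails before any compute.
#'
#' @param reference path to the reference Doppler volume (NIfTI).
#' @param atlas path to the atlas label volume (NIfTI, with its
#'   `_ontology.csv` alongside).
#' @param ref_to_atlas path to the pre-computed reference-to-atlas affine
#'   (JSON), or `NULL` for identity (reference already in atlas space).
#' @param mi an [mi_config()].
#' @param clip_percentiles normalization percentiles.
#' @param seed session seed, recorded in all provenance blocks.
#' @return A `bps_config`.
#' @export
bps_config <- function(reference, atlas, ref_to_atlas = NULL,
                       mi = mi_config(), clip_percentiles = c(1, 99),
                       seed = 0) {
  for (p in c(reference, atlas, ref_to_atlas)) {
    if (!is.null(p) && !file.exists(p))
      stop(errorCondition(paste0("configuration error: missing file ", p),
                          class = c("fusbps_config_error", "error")))
  }
  if (!file.exists(ontology_path(atlas)))
    stop(errorCondition(paste0("configuration error: missing ontology CSV ",
                               ontology_path(atlas)),
                        class = c("fusbps_config_error", "error")))
  structure(list(reference = reference, atlas = atlas,
                 ref_to_atlas = ref_to_atlas, mi = mi,
                 clip_percentiles = clip_percentiles, seed = seed),
            class = "bps_config")
}

#' Run the brain-positioning pipeline on a subject volume
#'
#' Chains normalization, affine registration of the subject volume to the
#' Doppler reference, composition with the reference-to-atlas transform and
#' nearest-neighbour label propagation onto the subject grid. Artifacts
#' (transform JSON, labelled NIfTI, markdown QC report, provenance JSON) are
#' written to `out_dir`; QC artifacts are still written when registration
#' fails.
#'
#' @param config a [bps_config()].
#' @param subject a [doppler_volume()] (raw Power Doppler; normalized
#'   internally).
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return list(subject_to_ref, subject_to_atlas, mi, labels, xcorr,
#'   provenance).
#' @export
run_bps <- function(config, subject, out_dir = NULL) {
  stopifnot(inherits(config, "bps_config"), inherits(subject, "doppler_volume"))
  config$mi$seed <- config$seed
  reference <- read_volume(config$reference)
  atlas <- read_atlas(config$atlas)
  ref_to_atlas <- if (is.null(config$ref_to_atlas)) affine3d()
  else read_affine(config$ref_to_atlas)
  t0 <- Sys.time()
  ref_n <- normalize_for_registration(reference, config$clip_percentiles)
  sub_n <- normalize_for_registration(subject, config$clip_percentiles)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reg <- tryCatch(register_affine(sub_n, ref_n, config$mi),
                  fusbps_registration_failure = function(e) e)
  failed <- inherits(reg, "error")
  prov <- list(config_hash = config_hash(config[c("reference", "atlas",
                                                  "ref_to_atlas", "mi",
                                                  "clip_percentiles")]),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("fusbps")),
               elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               failed = failed)
  if (failed) {
    if (!is.null(out_dir)) {
      writeLines(c("# BPS QC report", "", "registration FAILED:",
                   conditionMessage(reg)),
                 file.path(out_dir, "qc_report.md"))
      jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    stop(reg)
  }
  subject_to_atlas <- compose_transforms(ref_to_atlas, reg$transform)
  labels <- propagate_labels(atlas, subject_to_atlas, grid_of(subject))
  moved <- resample_volume(sub_n, reg$transform, grid_of(ref_n))
  xc <- tryCatch(xcorr_metrics(normalized_xcorr3(ref_n, moved)),
                 error = function(e) NULL)
  message(sprintf("bps: registered (MI %.3f nats) | ncc peak %.3f | %d labels | %.1fs",
                  reg$mi, xc$peak_value %||% NA, length(setdiff(unique(as.vector(labels)), 0)),
                  prov$elapsed_s))
  if (!is.null(out_dir)) {
    write_affine(reg$transform, file.path(out_dir, "subject_to_ref.json"))
    write_affine(subject_to_atlas, file.path(out_dir, "subject_to_atlas.json"))
    write_volume(doppler_volume(labels + 0, subject$spacing,
                                subject$origin_mm),
                 file.path(out_dir, "labels.nii.gz"))
    qc <- c("# BPS QC report", "",
            sprintf("- final mutual information: %.4f nats", reg$mi),
            sprintf("- per-level iterations: %s",
                    paste(vapply(reg$levels, function(l)
                      l$iterations %||% 0L, 0L), collapse = ", ")),
            if (!is.null(xc)) c(
              sprintf("- NCC peak value: %.3f", xc$peak_value),
              sprintf("- NCC peak lag (mm): %s",
                      paste(round(xc$peak_lag_mm, 3), collapse = ", ")),
              sprintf("- NCC FWHM (mm): %s",
                      paste(round(xc$fwhm_mm, 3), collapse = ", "))),
            sprintf("- propagated labels: %d regions",
                    length(setdiff(unique(as.vector(labels)), 0))),
            sprintf("- config hash %s, seed %d", prov$config_hash, prov$seed))
    writeLines(qc, file.path(out_dir, "qc_report.md"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(subject_to_ref = reg$transform, subject_to_atlas = subject_to_atlas,
       mi = reg$mi, labels = labels, xcorr = xc, provenance = prov)
}

#' Write / read a stimulus pattern as JSON
#'
#' @param stimulus a [stimulus_pattern()].
#' @param path JSON path.
#' @return `read_stimulus` returns the [stimulus_pattern()].
#' @export
write_stimulus <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "stimulus_pattern"))
  jsonlite::write_json(unclass(stimulus)[c("baseline_s", "n_trials", "on_s",
                                           "off_s")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_pattern(o$baseline_s, o$n_trials, o$on_s, o$off_s)
}

#' Write / read a stage pose as JSON
#'
#' @param pose a [stage_pose()].
#' @param path JSON path.
#' @return `read_pose` returns the [stage_pose()].
#' @export
write_pose <- function(pose, path) {
  stopifnot(inherits(pose, "stage_pose"))
  jsonlite::write_json(unclass(pose), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pose
#' @export
read_pose <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stage_pose(o$x_mm, o$y_mm, o$z_mm, o$yaw_deg)
}
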