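# End-to-end orchestration: stack cleaning -> pair alignment -> tomogram
# positioning -> patch tracking + model solution -> CTF -> reconstruction,
# with the quality metrics surfaced per series.

#' Pipeline configuration
#' @param do_ctf run CTF determination.
#' @param do_reconstruct run thickness estimation + final reconstruction.
#' @param tracker a [tracker_config()].
#' @param cleaner a [cleaner_config()].
#' @param reconstruction a [reconstruction_config()].
#' @param optics a [ctf_optics()].
#' @param seed deterministic seed recorded in reports.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(do_ctf = TRUE, do_reconstruct = TRUE,
                            tracker = tracker_config(),
                            cleaner = cleaner_config(),
                            reconstruction = reconstruction_config(),
                            optics = ctf_optics(), seed = 1) {
  structure(list(do_ctf = do_ctf, do_reconstruct = do_reconstruct,
                 tracker = tracker, cleaner = cleaner,
                 reconstruction = reconstruction, optics = optics,
                 seed = seed), class = "pipeline_config")
}

#' Run the full processing pipeline on a tilt series
#'
#' Stages, in order: stack cleaner (histogram correlation), coarse pair
#' alignment (skip-ahead cross-correlation), tomogram positioning (flow,
#' triangulation, robust plane fit, pre-tilt correction), patch tracking
#' and projection-model solution, single-resample alignment of the raw
#' stack, CTF determination, thickness estimation and final SIRT
#' reconstruction.  Warnings from individual stages accumulate in the
#' result; fatal errors propagate with the stage name.
#'
#' @param series a `tilt_series` (or an MRC path plus `metadata` passed to
#'   [read_tilt_series()]).
#' @param config a [pipeline_config()].
#' @param metadata optional metadata when `series` is a path.
#' @return list of class `pipeline_result`: `series` (aligned flags),
#'   `aligned` (aligned stack), `model`, `pair`, `positioning`, `ctf`,
#'   `tomogram`, `metrics` (a `quality_metrics`), `warnings`.
#' @export
run_pipeline <- function(series, config = pipeline_config(),
                         metadata = NULL) {
  if (is.character(series))
    series <- read_tilt_series(series, metadata)
  warns <- character(0)
  grab <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  run <- function(stage, expr) {
    tryCatch(grab(stage, expr), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cleaned <- run("stack_cleaner", clean_stack(series, config$cleaner))
  series <- cleaned$series

  pair <- run("coarse_align", align_pairs(series))
  series <- pair$series            # now in by-tilt order
  nominal_angles <- series$meta$tilt_angle_deg
  coarse <- run("coarse_align", apply_pair_alignment(pair))

  pos <- run("positioning", estimate_pretilt(coarse))
  series <- apply_pretilt_correction(series, pos$fit)
  coarse <- apply_pretilt_correction(coarse, pos$fit)

  trk <- run("fine_align", track_patches(coarse, config$tracker))
  model <- run("fine_align",
               solve_alignment(trk, series$meta$tilt_angle_deg,
                               series$nominal_tilt_axis_deg,
                               x_tilt_deg = pos$fit$x_tilt_deg))
  # model-guided re-tracking removes the expansion/rotation gradients from
  # the patch correlations, then the model is solved once more
  trk <- run("fine_align",
             tryCatch(track_patches(coarse, config$tracker, model = model),
                      error = function(e) trk))
  series$meta$usable <- trk$usable
  model <- run("fine_align",
               solve_alignment(trk, series$meta$tilt_angle_deg,
                               series$nominal_tilt_axis_deg,
                               x_tilt_deg = pos$fit$x_tilt_deg))
  series$extra$nominal_tilt_deg <- nominal_angles
  aligned <- run("fine_align", apply_alignment(series, model,
                                               pair$shift_table))
  aligned$extra$x_tilt_deg <- pos$fit$x_tilt_deg

  ctf <- NULL
  if (config$do_ctf)
    ctf <- run("ctf", fit_ctf_series(aligned, config$optics))

  tomo <- NULL
  thick <- NULL
  if (config$do_reconstruct) {
    thick <- run("reconstruct",
                 estimate_thickness(aligned, n_iterations =
                   min(15L, config$reconstruction$n_iterations)))
    tomo <- run("reconstruct",
                final_reconstruct(aligned,
                                  thickness = thick$thickness_voxels,
                                  config = config$reconstruction))
  }
  metrics <- compute_quality_metrics(model, series, ctf)
  structure(list(series = series, aligned = aligned, model = model,
                 pair = pair, positioning = pos, tracking = trk,
                 ctf = ctf, thickness = thick, tomogram = tomo,
                 metrics = metrics, warnings = warns,
                 config = config), class = "pipeline_result")
}

#' Assemble the per-series quality metrics
#'
#' The metrics mirrored in the processing report: alignment accuracy (mean
#' model residual in pixels), number of deleted slices (union of cleaner,
#' pair-alignment and tracking removals), tilt-axis correction (solved
#' minus nominal), defocus of the horizontal image, CTF confidence range
#' and astigmatism.
#'
#' @param model an `alignment_model`.
#' @param series the final `tilt_series` (flags reflect all removals).
#' @param ctf_fit a `ctf_series_fit` or NULL.
#' @return list of class `quality_metrics`.
#' @export
compute_quality_metrics <- function(model, series, ctf_fit = NULL) {
  hz <- if (!is.null(ctf_fit)) ctf_fit$horizontal_index else
    zero_tilt_index(series)
  structure(list(
    alignment_accuracy_px = model$mean_residual_px,
    n_deleted_slices = sum(!series$meta$usable),
    tilt_axis_correction_deg =
      model$tilt_axis_deg - series$nominal_tilt_axis_deg,
    defocus_um = if (!is.null(ctf_fit)) ctf_fit$defocus_um[hz] else
      NA_real_,
    ctf_confidence_range_A = if (!is.null(ctf_fit))
      ctf_fit$confidence_range_A else NA_real_,
    astigmatism_um = if (!is.null(ctf_fit)) ctf_fit$astig_um else
      NA_real_), class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("Alignment accuracy: %.3f px | Deleted slices: %d | ",
           "Tilt-axis correction: %.2f deg\nDefocus: %.2f um | ",
           "CTF confidence: %.1f A | Astigmatism: %.3f um\n"),
    x$alignment_accuracy_px, x$n_deleted_slices,
    x$tilt_axis_correction_deg, x$defocus_um, x$ctf_confidence_range_A,
    x$astigmatism_um))
  invisible(x)
}

#' Write the full export bundle for a processed series
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory.
#' @param base basename for the files.
#' @return list of all written paths.
#' @export
export_all <- function(result, out_dir, base = "series") {
  bundle <- export_imod(result$model, result$series,
                        result$pair$shift_table, out_dir, base)
  rel <- export_relion(result$series, result$model, result$ctf, out_dir,
                       base)
  defocus <- NULL
  if (!is.null(result$ctf)) {
    defocus <- file.path(out_dir, paste0(base, ".defocus"))
    export_ctfplotter(result$ctf, result$series, defocus)
  }
  report <- file.path(out_dir, paste0(base, "_report.json"))
  jsonlite::write_json(
    list(metrics = unclass(result$metrics),
         warnings = result$warnings,
         usable = result$series$meta$usable,
         tilt_axis_deg = result$model$tilt_axis_deg),
    report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(unclass(bundle), rel, list(defocus = defocus, report = report))
}
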