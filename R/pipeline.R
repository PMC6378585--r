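#' @include parallel.R postprocess.R render.R calibrate.R
NULL

#' Run the full localization pipeline on one movie
#'
#' Mirrors the four-stage workflow: open the movie, localize in parallel
#' over an interleaved worker plan, merge in frame order, apply the
#' automated postprocessing chain, and render preview images.  All
#' outputs land in a job-numbered subdirectory next to the input movie:
#' the raw localization CSV, the postprocessed CSV (file name embeds the
#' step tokens), preview images tagged 2D/3D, the drift graph when drift
#' correction ran, and a human-readable log.
#'
#' @param input movie path (TIFF/OME-TIFF).
#' @param calibration optional calibration file path or
#'   \linkS4class{AstigCalibration}; its presence triggers 3D processing.
#' @param n_nodes,jobs_per_node worker topology; the effective worker
#'   count is \code{n_nodes * jobs_per_node} (capped at the frame count).
#' @param engine "nwls", "mle" or "phasor".
#' @param detection a \linkS4class{DetectionParams}.
#' @param post a \linkS4class{PostprocessConfig} or a comma-separated
#'   token string such as \code{"minphot,sigma,drift"}.
#' @param render a \linkS4class{RenderSettings}.
#' @param preview write preview images when TRUE.
#' @param camera optional \linkS4class{CameraModel} override.
#' @param output_dir output directory (default: job-numbered subdirectory
#'   next to the input).
#' @param backend "fork" or "serial" worker execution.
#' @return list with elements \code{report} (\linkS4class{RunReport}),
#'   \code{raw} and \code{post} (\linkS4class{LocalizationTable}s),
#'   \code{output_dir} and \code{files} (named character vector).
#' @export
runPipeline <- function(input, calibration = NULL, n_nodes = 1L,
                        jobs_per_node = 1L, engine = "nwls",
                        detection = detectionParams(),
                        post = postprocessConfig(),
                        render = renderSettings(), preview = TRUE,
                        camera = NULL, output_dir = NULL,
                        backend = "fork") {
    if (is.character(post)) post <- postprocessConfig(steps = post)
    if (is.character(calibration)) calibration <- readCalibration(calibration)
    handle <- openMovie(input, camera_override = camera)
    W <- max(1L, min(as.integer(n_nodes) * as.integer(jobs_per_node),
                     handle@n_frames))
    plan <- planInterleave(handle@n_frames, W)
    if (is.null(output_dir))
        output_dir <- file.path(dirname(input), .job_id())
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    report <- runParallel(handle, plan, engine = engine,
                          detection = detection, calibration = calibration,
                          output_dir = output_dir, backend = backend)
    raw <- report@table
    log_path <- report@log_path
    tag <- if (is.null(calibration)) "2D" else "3D"
    files <- c(raw = report@merged_path, log = log_path)
    drift_png <- file.path(output_dir, "drift_correction.png")
    post_tab <- applyFilterChain(raw, post,
                                 pixel_size_nm = handle@camera@pixel_size_nm,
                                 drift_plot_path = if ("drift" %in% post@steps)
                                     drift_png else NULL)
    post_path <- file.path(output_dir, sprintf(
        "localizations_post_%s.csv", paste(post@steps, collapse = "-")))
    writeLocalizations(post_tab, post_path)
    files["post"] <- post_path
    for (line in post_tab@provenance) .log_line(log_path, line)
    if ("drift" %in% post@steps && file.exists(drift_png))
        files["drift_graph"] <- drift_png
    if (preview) {
        base <- file.path(output_dir, paste0("preview_", tag))
        rendered <- if (tag == "3D") renderZProjection(post_tab, render)
                    else renderImage(post_tab, render, "ash")
        out <- writeRendered(rendered, base)
        files["preview_tif"] <- out[1]
        files["preview_png"] <- out[2]
        .log_line(log_path, paste0("preview (", tag, ", ash) -> ", out[2]))
    }
    .log_line(log_path, sprintf(
        "pipeline done: %d raw, %d postprocessed localizations",
        nLocalizations(raw), nLocalizations(post_tab)))
    list(report = report, raw = raw, post = post_tab,
         output_dir = output_dir, files = files)
}
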