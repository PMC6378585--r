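#' @include AllClasses.R
NULL

#' Number of frames
#' @param x a MovieHandle, SimulationConfig or GroundTruth.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "MovieHandle", function(x) x@n_frames)

#' @rdname nFrames
#' @export
setMethod("nFrames", "SimulationConfig", function(x) x@n_frames)

#' @rdname nFrames
#' @export
setMethod("nFrames", "GroundTruth", function(x) x@n_frames)

#' Camera model of an object
#' @param x a MovieHandle or SimulationConfig.
#' @return the \linkS4class{CameraModel}.
#' @export
setGeneric("camera", function(x) standardGeneric("camera"))

#' @rdname camera
#' @export
setMethod("camera", "MovieHandle", function(x) x@camera)

#' @rdname camera
#' @export
setMethod("camera", "SimulationConfig", function(x) x@camera)

#' Localization records as a data.frame
#' @param x a LocalizationTable.
#' @return data.frame of records.
#' @export
setGeneric("locData", function(x) standardGeneric("locData"))

#' @rdname locData
#' @export
setMethod("locData", "LocalizationTable", function(x) x@records)

#' Dimensionality (2 or 3) of a localization table
#' @param x a LocalizationTable.
#' @return 2L or 3L.
#' @export
setGeneric("locDim", function(x) standardGeneric("locDim"))

#' @rdname locDim
#' @export
setMethod("locDim", "LocalizationTable", function(x) x@dim)

#' Processing provenance lines
#' @param x a LocalizationTable.
#' @return character vector of processing-step descriptions.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "LocalizationTable", function(x) x@provenance)

#' Number of localizations
#' @param x a LocalizationTable.
#' @return integer record count.
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))

#' @rdname nLocalizations
#' @export
setMethod("nLocalizations", "LocalizationTable",
          function(x) nrow(x@records))

#' Worker frame assignments
#' @param x a WorkerPlan.
#' @return list of integer frame vectors, one per worker.
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname assignments
#' @export
setMethod("assignments", "WorkerPlan", function(x) x@assignments)

setMethod("show", "CameraModel", function(object) {
    cat(sprintf("CameraModel: %g nm/px, %g photons/ADU, baseline %g ADU\n",
                object@pixel_size_nm, object@photons_per_adu,
                object@baseline_adu))
})

setMethod("show", "MovieHandle", function(object) {
    cat(sprintf("MovieHandle: %s\n  %d frames of %d x %d px\n",
                object@path, object@n_frames, object@height, object@width))
    show(object@camera)
})

setMethod("show", "LocalizationTable", function(object) {
    cat(sprintf("LocalizationTable (%dD): %d localizations",
                object@dim, nrow(object@records)))
    if (nrow(object@records))
        cat(sprintf(", frames %d..%d", min(object@records$frame),
                    max(object@records$frame)))
    cat("\n")
    if (length(object@provenance))
        cat("  provenance:", length(object@provenance), "step(s); last:",
            utils::tail(object@provenance, 1), "\n")
})

setMethod("show", "AstigCalibration", function(object) {
    cat(sprintf(paste0("AstigCalibration (%s):\n",
                       "  x: sigma0 %.1f nm, c %.1f nm, d %.1f nm\n",
                       "  y: sigma0 %.1f nm, c %.1f nm, d %.1f nm\n",
                       "  z range [%.0f, %.0f] nm\n"),
                object@engine_tag,
                object@sigma0_x_nm, object@c_x_nm, object@d_x_nm,
                object@sigma0_y_nm, object@c_y_nm, object@d_y_nm,
                object@z_min_nm, object@z_max_nm))
})

setMethod("show", "WorkerPlan", function(object) {
    cat(sprintf("WorkerPlan: %d frames over %d worker(s)\n",
                object@n_frames, object@n_workers))
    for (w in seq_len(min(object@n_workers, 4L))) {
        f <- object@assignments[[w]]
        cat(sprintf("  worker %d: %s%s (%d frames)\n", w,
                    paste(utils::head(f, 4), collapse = ", "),
                    if (length(f) > 4) ", ..." else "", length(f)))
    }
    if (object@n_workers > 4L) cat("  ...\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d emitters, %d ON events over %d frames\n",
                nrow(object@emitters), nrow(object@events), object@n_frames))
})

setMethod("show", "RunReport", function(object) {
    cat(sprintf("RunReport: %d worker(s), %d localizations\n",
                length(object@worker_counts), sum(object@worker_counts)))
    cat("  per-worker counts:", paste(object@worker_counts, collapse = ", "),
        "\n  merged table:", object@merged_path, "\n")
})
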