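#' @import methods
NULL

## Column schema of a localization table (internal names).  CSV headers in the
## ThunderSTORM dialect map onto these, see io-table.R.
.LOC_COLS_2D <- c("id", "frame", "x_nm", "y_nm", "sigma_nm",
                  "intensity_photons", "offset_photons", "bkgstd_photons",
                  "uncertainty_xy_nm")
.LOC_COLS_3D <- c(.LOC_COLS_2D,
                  "z_nm", "sigma1_nm", "sigma2_nm", "uncertainty_z_nm")

#' Camera model
#'
#' Describes how raw digital counts (ADU) map onto detected photons:
#' \code{photons = (ADU - baseline_adu) * photons_per_adu}, plus the physical
#' size of a camera pixel in the sample plane.
#'
#' @slot pixel_size_nm nm per camera pixel (> 0).
#' @slot photons_per_adu photons per digital count (> 0).
#' @slot baseline_adu dark offset in counts (>= 0).
#' @export
setClass("CameraModel",
         representation(pixel_size_nm = "numeric",
                        photons_per_adu = "numeric",
                        baseline_adu = "numeric"))

setValidity("CameraModel", function(object) {
    msg <- character()
    if (length(object@pixel_size_nm) != 1 || !is.finite(object@pixel_size_nm) ||
        object@pixel_size_nm <= 0)
        msg <- c(msg, "pixel_size_nm must be a single positive number")
    if (length(object@photons_per_adu) != 1 || !is.finite(object@photons_per_adu) ||
        object@photons_per_adu <= 0)
        msg <- c(msg, "photons_per_adu must be a single positive number")
    if (length(object@baseline_adu) != 1 || !is.finite(object@baseline_adu) ||
        object@baseline_adu < 0)
        msg <- c(msg, "baseline_adu must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Construct a CameraModel
#'
#' @param pixel_size_nm nm per camera pixel.
#' @param photons_per_adu photons per digital count.
#' @param baseline_adu dark offset in counts.
#' @return A \linkS4class{CameraModel}.
#' @examples
#' cameraModel(100, 0.5, 100)
#' @export
cameraModel <- function(pixel_size_nm, photons_per_adu, baseline_adu = 0) {
    new("CameraModel", pixel_size_nm = as.numeric(pixel_size_nm),
        photons_per_adu = as.numeric(photons_per_adu),
        baseline_adu = as.numeric(baseline_adu))
}

#' Movie handle
#'
#' A lazily readable TIFF/OME-TIFF time series with camera metadata.  Frames
#' are addressed 1..n_frames; pixel values are raw counts (ADU).  Only the
#' frames requested by \code{\link{readFrames}} are ever resident in memory.
#'
#' @slot path path to the TIFF file.
#' @slot n_frames number of frames.
#' @slot height,width frame dimensions in pixels.
#' @slot camera a \linkS4class{CameraModel}.
#' @export
setClass("MovieHandle",
         representation(path = "character", n_frames = "integer",
                        height = "integer", width = "integer",
                        camera = "CameraModel"))

setValidity("MovieHandle", function(object) {
    msg <- character()
    if (object@n_frames < 1L) msg <- c(msg, "n_frames must be >= 1")
    if (object@height < 8L || object@width < 8L)
        msg <- c(msg, "frames must be at least 8x8 pixels")
    if (length(msg)) msg else TRUE
})

#' Localization table
#'
#' Ordered records of emitter fits in physical units (nm, photons).  2D
#' tables carry columns id, frame, x_nm, y_nm, sigma_nm, intensity_photons,
#' offset_photons, bkgstd_photons, uncertainty_xy_nm; 3D tables add z_nm,
#' sigma1_nm, sigma2_nm and uncertainty_z_nm.
#'
#' @slot records data.frame of localization records.
#' @slot dim 2L or 3L.
#' @slot provenance ordered character vector of processing-step descriptions.
#' @export
setClass("LocalizationTable",
         representation(records = "data.frame", dim = "integer",
                        provenance = "character"))

setValidity("LocalizationTable", function(object) {
    msg <- character()
    if (!object@dim %in% c(2L, 3L)) msg <- c(msg, "dim must be 2 or 3")
    want <- if (identical(object@dim, 3L)) .LOC_COLS_3D else .LOC_COLS_2D
    if (!identical(names(object@records), want))
        msg <- c(msg, paste0("records must have columns: ",
                             paste(want, collapse = ", ")))
    n <- nrow(object@records)
    if (n > 0) {
        if (anyDuplicated(object@records$id))
            msg <- c(msg, "record ids must be unique")
        if (any(object@records$frame < 1))
            msg <- c(msg, "frame numbers must be >= 1")
        if (any(!is.finite(object@records$sigma_nm)) ||
            any(object@records$sigma_nm <= 0))
            msg <- c(msg, "sigma_nm must be positive and finite")
        if (any(!is.finite(object@records$intensity_photons)))
            msg <- c(msg, "intensity_photons must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a LocalizationTable
#'
#' @param records data.frame with the schema columns (missing optional
#'   uncertainty columns are filled with NA).
#' @param dim 2 or 3; inferred from the presence of a \code{z_nm} column
#'   when NULL.
#' @param provenance character vector of processing-step descriptions.
#' @return A \linkS4class{LocalizationTable}.
#' @export
localizationTable <- function(records, dim = NULL, provenance = character()) {
    if (is.null(dim)) dim <- if ("z_nm" %in% names(records)) 3L else 2L
    dim <- as.integer(dim)
    want <- if (dim == 3L) .LOC_COLS_3D else .LOC_COLS_2D
    for (cn in setdiff(want, names(records)))
        records[[cn]] <- if (cn %in% c("id", "frame"))
            integer(nrow(records)) else rep(NA_real_, nrow(records))
    records <- records[, want, drop = FALSE]
    rownames(records) <- NULL
    records$id <- as.integer(records$id)
    records$frame <- as.integer(records$frame)
    new("LocalizationTable", records = records, dim = dim,
        provenance = as.character(provenance))
}

#' Empty LocalizationTable
#' @param dim 2 or 3.
#' @return An empty \linkS4class{LocalizationTable}.
#' @export
emptyLocalizationTable <- function(dim = 2L) {
    dim <- as.integer(dim)
    cols <- if (dim == 3L) .LOC_COLS_3D else .LOC_COLS_2D
    rec <- as.data.frame(stats::setNames(
        lapply(cols, function(cn)
            if (cn %in% c("id", "frame")) integer(0) else numeric(0)), cols))
    new("LocalizationTable", records = rec, dim = dim,
        provenance = character())
}

#' Astigmatism calibration
#'
#' Defocus curves \eqn{\sigma(z) = \sigma_0 \sqrt{1 + ((z - c)/d)^2}} for the
#' x and y PSF widths, enabling z lookup from the ellipticity of an
#' astigmatic spot.  The two focal offsets \code{c_x_nm} and \code{c_y_nm}
#' must differ: astigmatism encodes z in the difference of the two widths.
#'
#' @slot sigma0_x_nm,c_x_nm,d_x_nm waist, focal offset and depth scale of the
#'   x-width curve (nm).
#' @slot sigma0_y_nm,c_y_nm,d_y_nm same for the y-width curve.
#' @slot z_min_nm,z_max_nm validity range of the calibration.
#' @slot engine_tag "gaussian" or "phasor" (which width estimator the curves
#'   were fitted against).
#' @export
setClass("AstigCalibration",
         representation(sigma0_x_nm = "numeric", c_x_nm = "numeric",
                        d_x_nm = "numeric",
                        sigma0_y_nm = "numeric", c_y_nm = "numeric",
                        d_y_nm = "numeric",
                        z_min_nm = "numeric", z_max_nm = "numeric",
                        engine_tag = "character"))

setValidity("AstigCalibration", function(object) {
    msg <- character()
    if (object@sigma0_x_nm <= 0 || object@sigma0_y_nm <= 0)
        msg <- c(msg, "waists sigma0 must be positive")
    if (object@d_x_nm <= 0 || object@d_y_nm <= 0)
        msg <- c(msg, "depth scales d must be positive")
    if (isTRUE(all.equal(object@c_x_nm, object@c_y_nm)))
        msg <- c(msg, "focal offsets c_x and c_y must differ (astigmatism)")
    if (object@z_min_nm >= object@z_max_nm)
        msg <- c(msg, "z_min_nm must be < z_max_nm")
    if (!object@engine_tag %in% c("gaussian", "phasor"))
        msg <- c(msg, "engine_tag must be 'gaussian' or 'phasor'")
    if (length(msg)) msg else TRUE
})

#' Construct an AstigCalibration
#'
#' @param sigma0_x_nm,c_x_nm,d_x_nm x-axis defocus parameters (nm).
#' @param sigma0_y_nm,c_y_nm,d_y_nm y-axis defocus parameters (nm).
#' @param z_min_nm,z_max_nm validity range (nm).
#' @param engine_tag "gaussian" or "phasor".
#' @return An \linkS4class{AstigCalibration}.
#' @export
astigCalibration <- function(sigma0_x_nm, c_x_nm, d_x_nm,
                             sigma0_y_nm, c_y_nm, d_y_nm,
                             z_min_nm = -500, z_max_nm = 500,
                             engine_tag = "gaussian") {
    new("AstigCalibration",
        sigma0_x_nm = as.numeric(sigma0_x_nm), c_x_nm = as.numeric(c_x_nm),
        d_x_nm = as.numeric(d_x_nm),
        sigma0_y_nm = as.numeric(sigma0_y_nm), c_y_nm = as.numeric(c_y_nm),
        d_y_nm = as.numeric(d_y_nm),
        z_min_nm = as.numeric(z_min_nm), z_max_nm = as.numeric(z_max_nm),
        engine_tag = engine_tag)
}

#' Spot detection parameters
#'
#' @slot dog_sigma1_px,dog_sigma2_px band-pass (difference-of-Gaussians)
#'   scales in pixels, sigma1 < sigma2.
#' @slot k_threshold detection threshold in multiples of the robust
#'   (MAD-based) standard deviation of the filtered frame.
#' @slot roi_radius_px integer half-width of the fitting region.
#' @export
setClass("DetectionParams",
         representation(dog_sigma1_px = "numeric", dog_sigma2_px = "numeric",
                        k_threshold = "numeric", roi_radius_px = "integer"))

setValidity("DetectionParams", function(object) {
    msg <- character()
    if (object@dog_sigma1_px <= 0 || object@dog_sigma1_px >= object@dog_sigma2_px)
        msg <- c(msg, "need 0 < dog_sigma1_px < dog_sigma2_px")
    if (object@k_threshold <= 0) msg <- c(msg, "k_threshold must be positive")
    if (object@roi_radius_px < 2L) msg <- c(msg, "roi_radius_px must be >= 2")
    if (length(msg)) msg else TRUE
})

#' Construct DetectionParams
#'
#' Defaults: DoG scales 1.0 / 1.6 px, threshold 3 robust SDs, ROI radius
#' 3 px (use 4 px for astigmatic 3D, where spots are elliptical).
#'
#' @param dog_sigma1_px,dog_sigma2_px band-pass scales (px).
#' @param k_threshold threshold in robust SDs of the filtered frame.
#' @param roi_radius_px ROI half-width (px).
#' @return A \linkS4class{DetectionParams}.
#' @export
detectionParams <- function(dog_sigma1_px = 1.0, dog_sigma2_px = 1.6,
                            k_threshold = 3, roi_radius_px = 3L) {
    new("DetectionParams", dog_sigma1_px = as.numeric(dog_sigma1_px),
        dog_sigma2_px = as.numeric(dog_sigma2_px),
        k_threshold = as.numeric(k_threshold),
        roi_radius_px = as.integer(roi_radius_px))
}

#' Simulation configuration
#'
#' Parameters of the synthetic dSTORM movie generator: field size, camera,
#' emitter placement, blinking/bleaching photophysics, PSF, noise and drift.
#'
#' @slot width,height field size in pixels.
#' @slot n_frames number of frames.
#' @slot camera a \linkS4class{CameraModel}.
#' @slot structure "uniform", "filaments" or "grid".
#' @slot n_emitters number of emitters.
#' @slot p_on per-frame activation probability of an unbleached emitter.
#' @slot p_bleach probability of permanent bleaching after each ON event.
#' @slot photons_mean,photons_sd mean and spread (lognormal) of photons per
#'   ON event.
#' @slot background_photons mean background photons/pixel/frame.
#' @slot read_noise_e Gaussian read noise, electrons RMS.
#' @slot psf_sigma_nm in-focus PSF width (nm).
#' @slot astig optional \linkS4class{AstigCalibration} used generatively (3D).
#' @slot z_range_nm axial placement range, length-2 (3D) or c(0,0) for 2D.
#' @slot drift_nm_per_frame lateral drift velocity (vx, vy) nm/frame.
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
         representation(width = "integer", height = "integer",
                        n_frames = "integer", camera = "CameraModel",
                        structure = "character", n_emitters = "integer",
                        p_on = "numeric", p_bleach = "numeric",
                        photons_mean = "numeric", photons_sd = "numeric",
                        background_photons = "numeric", read_noise_e = "numeric",
                        psf_sigma_nm = "numeric", astig = "ANY",
                        z_range_nm = "numeric", drift_nm_per_frame = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@p_on <= 0 || object@p_on > 1)
        msg <- c(msg, "p_on must be in (0, 1]")
    if (object@p_bleach < 0 || object@p_bleach > 1)
        msg <- c(msg, "p_bleach must be in [0, 1]")
    if (object@photons_mean <= 0) msg <- c(msg, "photons_mean must be > 0")
    if (object@psf_sigma_nm <= 0) msg <- c(msg, "psf_sigma_nm must be > 0")
    if (!object@structure %in% c("uniform", "filaments", "grid"))
        msg <- c(msg, "structure must be uniform, filaments or grid")
    if (length(object@z_range_nm) != 2)
        msg <- c(msg, "z_range_nm must have length 2")
    if (length(object@drift_nm_per_frame) != 2)
        msg <- c(msg, "drift_nm_per_frame must have length 2 (vx, vy)")
    if (!is.null(object@astig) && !is(object@astig, "AstigCalibration"))
        msg <- c(msg, "astig must be NULL or an AstigCalibration")
    if (diff(object@z_range_nm) != 0 && is.null(object@astig))
        msg <- c(msg, "non-zero z_range_nm requires an astig calibration")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe a typical dSTORM acquisition at desk scale: 64x64 px
#' field, 100 nm pixels, 130 nm PSF width, 1000 photons per ON event,
#' 10 background photons/pixel/frame, 1.6 e- read noise, baseline 100 ADU
#' at 0.5 photons/ADU.
#'
#' @param width,height field size (px).
#' @param n_frames number of frames.
#' @param camera \linkS4class{CameraModel}.
#' @param structure emitter placement: "uniform", "filaments" or "grid".
#' @param n_emitters number of emitters.
#' @param p_on per-frame activation probability.
#' @param p_bleach per-ON-event permanent bleach probability.
#' @param photons_mean,photons_sd lognormal photons per ON event.
#' @param background_photons mean background photons/pixel/frame.
#' @param read_noise_e read noise (electrons RMS).
#' @param psf_sigma_nm in-focus PSF width.
#' @param astig optional \linkS4class{AstigCalibration} (3D generative model).
#' @param z_range_nm axial placement range (length 2).
#' @param drift_nm_per_frame lateral drift (vx, vy) nm/frame.
#' @param seed RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(width = 64L, height = 64L, n_frames = 100L,
                             camera = cameraModel(100, 0.5, 100),
                             structure = "filaments", n_emitters = 200L,
                             p_on = 0.01, p_bleach = 0, photons_mean = 1000,
                             photons_sd = 200, background_photons = 10,
                             read_noise_e = 1.6, psf_sigma_nm = 130,
                             astig = NULL, z_range_nm = c(0, 0),
                             drift_nm_per_frame = c(0, 0), seed = 1L) {
    new("SimulationConfig", width = as.integer(width),
        height = as.integer(height), n_frames = as.integer(n_frames),
        camera = camera, structure = structure,
        n_emitters = as.integer(n_emitters), p_on = as.numeric(p_on),
        p_bleach = as.numeric(p_bleach), photons_mean = as.numeric(photons_mean),
        photons_sd = as.numeric(photons_sd),
        background_photons = as.numeric(background_photons),
        read_noise_e = as.numeric(read_noise_e),
        psf_sigma_nm = as.numeric(psf_sigma_nm), astig = astig,
        z_range_nm = as.numeric(z_range_nm),
        drift_nm_per_frame = as.numeric(drift_nm_per_frame),
        seed = as.integer(seed))
}

#' Simulated ground truth
#'
#' Emitter positions, per-frame ON events with photon counts, and the
#' per-frame cumulative drift used when rendering.  Event positions as
#' imaged are \code{emitters[emitter, ] + drift[frame, ]}.
#'
#' @slot emitters numeric matrix (n_emitters x 3): x_nm, y_nm, z_nm.
#' @slot events data.frame: frame, emitter, photons.
#' @slot drift numeric matrix (n_frames x 2): cumulative dx_nm, dy_nm.
#' @slot n_frames number of frames.
#' @export
setClass("GroundTruth",
         representation(emitters = "matrix", events = "data.frame",
                        drift = "matrix", n_frames = "integer"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (nrow(object@events) > 0) {
        if (any(object@events$frame < 1) ||
            any(object@events$frame > object@n_frames))
            msg <- c(msg, "event frames must lie in [1, n_frames]")
        if (any(object@events$photons <= 0))
            msg <- c(msg, "event photons must be positive")
    }
    if (nrow(object@drift) != object@n_frames)
        msg <- c(msg, "drift must have one row per frame")
    if (length(msg)) msg else TRUE
})

#' Interleaved worker plan
#'
#' Assignment of frames to workers: worker w of W processes the frames
#' \code{f} with \code{(f - 1) mod W == w - 1}.  Assignments partition
#' 1..n_frames and their sizes differ by at most one.
#'
#' @slot n_frames number of frames.
#' @slot n_workers number of workers W.
#' @slot assignments list of integer frame vectors, one per worker.
#' @export
setClass("WorkerPlan",
         representation(n_frames = "integer", n_workers = "integer",
                        assignments = "list"))

setValidity("WorkerPlan", function(object) {
    msg <- character()
    all_frames <- sort(unlist(object@assignments))
    if (!identical(all_frames, seq_len(object@n_frames)))
        msg <- c(msg, "assignments must partition 1..n_frames")
    sizes <- lengths(object@assignments)
    if (length(sizes) && diff(range(sizes)) > 1L)
        msg <- c(msg, "assignment sizes must differ by at most 1")
    if (length(msg)) msg else TRUE
})

#' Drift trajectory
#'
#' Per-frame lateral displacement relative to the first temporal bin,
#' re-referenced so frame 1 has displacement exactly (0, 0).
#'
#' @slot frames integer frame numbers 1..F.
#' @slot dx_nm,dy_nm per-frame displacement (nm).
#' @export
setClass("DriftTrajectory",
         representation(frames = "integer", dx_nm = "numeric",
                        dy_nm = "numeric"))

setValidity("DriftTrajectory", function(object) {
    msg <- character()
    n <- length(object@frames)
    if (length(object@dx_nm) != n || length(object@dy_nm) != n)
        msg <- c(msg, "frames, dx_nm and dy_nm must have equal length")
    if (n > 0 && (abs(object@dx_nm[1]) > 1e-9 || abs(object@dy_nm[1]) > 1e-9))
        msg <- c(msg, "frame 1 displacement must be (0, 0)")
    if (any(!is.finite(object@dx_nm)) || any(!is.finite(object@dy_nm)))
        msg <- c(msg, "displacements must be finite")
    if (length(msg)) msg else TRUE
})

#' Postprocessing configuration
#'
#' Ordered chain of postprocessing steps with their parameters.  Tokens:
#' \describe{
#'   \item{minphot}{keep intensity >= min_intensity_photons (default 1;
#'     removes unphysical sub-photon fits).}
#'   \item{sigma}{keep fitted widths within the
#'     [sigma_lo_centile, sigma_hi_centile] intercentile range (default
#'     10th-75th), centiles computed on the table as it stands.}
#'   \item{zunc}{keep axial uncertainty <= zunc_max_nm (default 500 nm);
#'     ignored for 2D tables.}
#'   \item{drift}{estimate and subtract lateral drift by cross-correlation.}
#'   \item{merge}{combine localizations of one emitter in consecutive frames.}
#' }
#'
#' @slot steps ordered character vector of step tokens.
#' @slot min_intensity_photons,zunc_max_nm filter thresholds.
#' @slot sigma_lo_centile,sigma_hi_centile intercentile bounds (percent).
#' @slot drift_bins,drift_magnification drift-estimation parameters.
#' @slot merge_radius_nm,merge_max_gap_frames consecutive-merge parameters.
#' @export
setClass("PostprocessConfig",
         representation(steps = "character",
                        min_intensity_photons = "numeric",
                        zunc_max_nm = "numeric",
                        sigma_lo_centile = "numeric",
                        sigma_hi_centile = "numeric",
                        drift_bins = "integer",
                        drift_magnification = "integer",
                        merge_radius_nm = "numeric",
                        merge_max_gap_frames = "integer"))

setValidity("PostprocessConfig", function(object) {
    msg <- character()
    bad <- setdiff(object@steps, c("minphot", "sigma", "zunc", "drift", "merge"))
    if (length(bad))
        msg <- c(msg, paste0("unknown postprocessing step token(s): ",
                             paste(bad, collapse = ", ")))
    if (object@sigma_lo_centile < 0 || object@sigma_hi_centile > 100 ||
        object@sigma_lo_centile >= object@sigma_hi_centile)
        msg <- c(msg, "need 0 <= sigma_lo_centile < sigma_hi_centile <= 100")
    if (object@drift_bins < 2L) msg <- c(msg, "drift_bins must be >= 2")
    if (object@merge_radius_nm <= 0) msg <- c(msg, "merge_radius_nm must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a PostprocessConfig
#'
#' Default step order: minphot, sigma, zunc, drift, merge.
#'
#' @param steps character vector (or single comma-separated string) of step
#'   tokens.
#' @param min_intensity_photons minimum photons (default 1).
#' @param zunc_max_nm maximum axial uncertainty (default 500).
#' @param sigma_lo_centile,sigma_hi_centile intercentile bounds (default
#'   10 and 75).
#' @param drift_bins temporal bins for drift estimation (default 5).
#' @param drift_magnification drift histogram magnification (default 5).
#' @param merge_radius_nm consecutive-merge capture radius (default 50).
#' @param merge_max_gap_frames allowed off frames inside a merged chain
#'   (default 0).
#' @return A \linkS4class{PostprocessConfig}.
#' @export
postprocessConfig <- function(steps = c("minphot", "sigma", "zunc",
                                        "drift", "merge"),
                              min_intensity_photons = 1,
                              zunc_max_nm = 500,
                              sigma_lo_centile = 10, sigma_hi_centile = 75,
                              drift_bins = 5L, drift_magnification = 5L,
                              merge_radius_nm = 50,
                              merge_max_gap_frames = 0L) {
    if (length(steps) == 1 && grepl(",", steps))
        steps <- strsplit(steps, ",")[[1]]
    steps <- trimws(steps)
    new("PostprocessConfig", steps = steps,
        min_intensity_photons = as.numeric(min_intensity_photons),
        zunc_max_nm = as.numeric(zunc_max_nm),
        sigma_lo_centile = as.numeric(sigma_lo_centile),
        sigma_hi_centile = as.numeric(sigma_hi_centile),
        drift_bins = as.integer(drift_bins),
        drift_magnification = as.integer(drift_magnification),
        merge_radius_nm = as.numeric(merge_radius_nm),
        merge_max_gap_frames = as.integer(merge_max_gap_frames))
}

#' Rendering settings
#'
#' @slot superpixel_nm output pixel size (default 20 nm).
#' @slot shifts average-shifted-histogram shifts per axis (default 2).
#' @slot gaussian_sigma_mode "fixed" or "uncertainty".
#' @slot gaussian_sigma_nm splat width when mode is "fixed".
#' @slot z_color_range_nm z colour range for 3D projections (default
#'   -400..+400 nm).
#' @slot colormap colour map name for z projections.
#' @export
setClass("RenderSettings",
         representation(superpixel_nm = "numeric", shifts = "integer",
                        gaussian_sigma_mode = "character",
                        gaussian_sigma_nm = "numeric",
                        z_color_range_nm = "numeric", colormap = "character"))

setValidity("RenderSettings", function(object) {
    msg <- character()
    if (object@superpixel_nm <= 0) msg <- c(msg, "superpixel_nm must be > 0")
    if (object@shifts < 1L) msg <- c(msg, "shifts must be >= 1")
    if (object@z_color_range_nm[1] >= object@z_color_range_nm[2])
        msg <- c(msg, "z colour range must have z_lo < z_hi")
    if (!object@gaussian_sigma_mode %in% c("fixed", "uncertainty"))
        msg <- c(msg, "gaussian_sigma_mode must be 'fixed' or 'uncertainty'")
    if (length(msg)) msg else TRUE
})

#' Construct RenderSettings
#'
#' @param superpixel_nm output pixel size.
#' @param shifts ASH shifts per axis.
#' @param gaussian_sigma_mode "fixed" or "uncertainty".
#' @param gaussian_sigma_nm splat width for mode "fixed".
#' @param z_color_range_nm length-2 z colour range.
#' @param colormap colour map name ("rainbow" or "viridis-like").
#' @return A \linkS4class{RenderSettings}.
#' @export
renderSettings <- function(superpixel_nm = 20, shifts = 2L,
                           gaussian_sigma_mode = "fixed",
                           gaussian_sigma_nm = 20,
                           z_color_range_nm = c(-400, 400),
                           colormap = "rainbow") {
    new("RenderSettings", superpixel_nm = as.numeric(superpixel_nm),
        shifts = as.integer(shifts),
        gaussian_sigma_mode = gaussian_sigma_mode,
        gaussian_sigma_nm = as.numeric(gaussian_sigma_nm),
        z_color_range_nm = as.numeric(z_color_range_nm),
        colormap = colormap)
}

#' Run report
#'
#' Summary of a parallel localization run: per-worker localization counts
#' and wall times, output paths, and the merged table.
#'
#' @slot worker_counts integer per-worker localization counts.
#' @slot worker_times_s numeric per-worker wall times (seconds).
#' @slot merged_path path to the merged raw CSV.
#' @slot log_path path to the concatenated log.
#' @slot output_dir run output directory.
#' @slot table the merged \linkS4class{LocalizationTable}.
#' @export
setClass("RunReport",
         representation(worker_counts = "integer", worker_times_s = "numeric",
                        merged_path = "character", log_path = "character",
                        output_dir = "character", table = "ANY"))

setValidity("RunReport", function(object) {
    if (is(object@table, "LocalizationTable") &&
        sum(object@worker_counts) != nrow(object@table@records))
        "sum of per-worker counts must equal merged table size"
    else TRUE
})
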