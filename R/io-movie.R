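#' @include AllClasses.R
NULL

## Camera metadata discovery, in order of precedence:
##   1. explicit camera override,
##   2. sidecar YAML "<movie basename>.camera.yaml" next to the movie
##      (keys pixel_size_nm, photons_per_adu, baseline_adu),
##   3. OME-XML ImageDescription (PhysicalSizeX, um -> nm) for the pixel
##      size only -- photon conversion must then come from a sidecar or
##      override.
.sidecar_path <- function(path)
    file.path(dirname(path),
              paste0(sub("\\.ome\\.tiff?$|\\.tiff?$", "",
                         basename(path), ignore.case = TRUE),
                     ".camera.yaml"))

.camera_from_sidecar <- function(path) {
    sc <- .sidecar_path(path)
    if (!file.exists(sc)) return(NULL)
    y <- yaml::read_yaml(sc)
    need <- c("pixel_size_nm", "photons_per_adu", "baseline_adu")
    miss <- setdiff(need, names(y))
    if (length(miss))
        .stop2("metadataError",
               paste0("camera sidecar ", sc, " missing key(s): ",
                      paste(miss, collapse = ", ")))
    cameraModel(y$pixel_size_nm, y$photons_per_adu, y$baseline_adu)
}

.ome_pixel_size_nm <- function(path) {
    meta <- tryCatch(tiff::readTIFF(path, payload = FALSE, all = 1),
                     error = function(e) NULL)
    desc <- attr(meta, "description")
    if (is.null(desc) && !is.null(meta) && "description" %in% names(meta))
        desc <- meta$description[1]
    if (is.null(desc) || !nzchar(desc)) return(NULL)
    m <- regmatches(desc, regexpr('PhysicalSizeX="[0-9.eE+-]+"', desc))
    if (!length(m)) return(NULL)
    um <- as.numeric(sub('PhysicalSizeX="([0-9.eE+-]+)"', "\\1", m))
    if (!is.finite(um)) return(NULL)
    um * 1000
}

#' Open a TIFF/OME-TIFF movie
#'
#' Creates a lazily readable handle on a TIFF time series.  Camera metadata
#' is taken from a sidecar YAML file (\code{<movie>.camera.yaml}, keys
#' \code{pixel_size_nm}, \code{photons_per_adu}, \code{baseline_adu}) or,
#' for the pixel size alone, from embedded OME-XML; an explicit
#' \code{camera_override} replaces any metadata.
#'
#' @param path path to the TIFF/OME-TIFF file.
#' @param camera_override optional \linkS4class{CameraModel} replacing
#'   metadata values.
#' @return A \linkS4class{MovieHandle}.
#' @examples
#' cfg <- simulationConfig(n_frames = 5L, n_emitters = 10L, seed = 7L)
#' paths <- renderMovie(generateGroundTruth(cfg), cfg,
#'                      file.path(tempdir(), "demo.ome.tif"))
#' mov <- openMovie(paths$movie)
#' nFrames(mov)
#' @export
openMovie <- function(path, camera_override = NULL) {
    if (!file.exists(path))
        .stop2("formatError", paste0("no such file: ", path))
    meta <- tryCatch(tiff::readTIFF(path, payload = FALSE, all = TRUE),
                     error = function(e)
                         .stop2("formatError",
                                paste0("not a readable TIFF time series: ",
                                       path, " (", conditionMessage(e), ")")))
    n <- nrow(meta)
    cam <- camera_override
    if (is.null(cam)) cam <- .camera_from_sidecar(path)
    if (is.null(cam)) {
        px <- .ome_pixel_size_nm(path)
        if (is.null(px))
            .stop2("metadataError",
                   paste0("no camera metadata for ", path,
                          ": missing pixel_size_nm (provide a ",
                          basename(.sidecar_path(path)),
                          " sidecar or a camera_override)"))
        .stop2("metadataError",
               paste0("no photon conversion metadata for ", path,
                      ": missing photons_per_adu (provide a sidecar or ",
                      "camera_override)"))
    }
    new("MovieHandle", path = path, n_frames = as.integer(n),
        height = as.integer(meta$length[1]), width = as.integer(meta$width[1]),
        camera = cam)
}

#' Frame numbers of a strided subset
#'
#' @param handle a \linkS4class{MovieHandle}.
#' @param start first frame (1-based).
#' @param stride step between frames.
#' @return integer vector start, start+stride, ... <= n_frames.
#' @export
frameSequence <- function(handle, start = 1L, stride = 1L) {
    start <- as.integer(start); stride <- as.integer(stride)
    if (start < 1L || start > handle@n_frames)
        .stop2("boundsError",
               sprintf("start frame %d outside 1..%d", start, handle@n_frames))
    if (stride < 1L) .stop2("boundsError", "stride must be >= 1")
    seq.int(start, handle@n_frames, by = stride)
}

#' Read a single frame
#'
#' @param handle a \linkS4class{MovieHandle}.
#' @param frame frame number (1-based).
#' @return numeric matrix of raw counts (ADU), height x width.
#' @export
readFrame <- function(handle, frame) {
    frame <- as.integer(frame)
    if (frame < 1L || frame > handle@n_frames)
        .stop2("boundsError",
               sprintf("frame %d outside 1..%d", frame, handle@n_frames))
    px <- tiff::readTIFF(handle@path, all = frame, as.is = TRUE)[[1]]
    storage.mode(px) <- "double"
    px
}

#' Read a strided subset of frames
#'
#' Returns the frames \code{start, start + stride, ...} as a list of
#' \code{(frame, pixels)} pairs.  Workers iterate frame-by-frame with
#' \code{\link{readFrame}} so at most one frame of a subset is resident at
#' a time; this convenience reader materializes only the requested subset,
#' never the full stack.
#'
#' @param handle a \linkS4class{MovieHandle}.
#' @param start first frame (1-based).
#' @param stride step between frames.
#' @return list of lists with elements \code{frame} (integer) and
#'   \code{pixels} (matrix of ADU counts).
#' @export
readFrames <- function(handle, start = 1L, stride = 1L) {
    frames <- frameSequence(handle, start, stride)
    lapply(frames, function(k) list(frame = k, pixels = readFrame(handle, k)))
}

#' Write a movie as multi-frame 16-bit TIFF
#'
#' Counts are clipped to the uint16 range.  A camera sidecar YAML is
#' written next to the movie so \code{\link{openMovie}} can recover the
#' metadata.
#'
#' @param frames list of numeric matrices (ADU counts).
#' @param path output TIFF path.
#' @param camera a \linkS4class{CameraModel} recorded in the sidecar.
#' @return the movie path, invisibly.
#' @export
writeMovie <- function(frames, path, camera) {
    stopifnot(length(frames) >= 1)
    scaled <- lapply(frames, function(f) {
        f <- pmin(pmax(round(f), 0), 65535)
        f / 65535
    })
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
    yaml::write_yaml(list(pixel_size_nm = camera@pixel_size_nm,
                          photons_per_adu = camera@photons_per_adu,
                          baseline_adu = camera@baseline_adu),
                     .sidecar_path(path))
    invisible(path)
}
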