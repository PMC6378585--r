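#' @include AllClasses.R postprocess.R
NULL

## Grid geometry shared by all render modes: origin at the floored data
## minimum, extent covering all records plus a one-super-pixel margin.
.render_grid <- function(rec, sp) {
    if (nrow(rec)) {
        x0 <- floor(min(rec$x_nm) / sp) * sp
        y0 <- floor(min(rec$y_nm) / sp) * sp
        nx <- ceiling((max(rec$x_nm) - x0) / sp) + 1L
        ny <- ceiling((max(rec$y_nm) - y0) / sp) + 1L
    } else { x0 <- y0 <- 0; nx <- ny <- 8L }
    list(x0 = x0, y0 = y0, nx = as.integer(nx), ny = as.integer(ny))
}

#' Render a localization table as a super-resolution image
#'
#' Modes: \code{histogram} (counts per super-pixel), \code{ash} (average
#' of \code{shifts^2} histograms whose origins are offset by fractions of
#' a super-pixel) and \code{gaussian} (each record splatted as a
#' normalized 2D Gaussian with sigma from the record uncertainty or a
#' fixed value).  Total image mass equals the record count (exactly for
#' histogram/ash, up to edge truncation for gaussian).  The table is
#' never modified.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param settings a \linkS4class{RenderSettings}.
#' @param mode "histogram", "ash" or "gaussian".
#' @return list with \code{image} (numeric matrix, rows = y), \code{origin}
#'   (nm coordinates of the image's (0,0) pixel corner) and
#'   \code{superpixel_nm}.
#' @export
renderImage <- function(table, settings = renderSettings(),
                        mode = c("histogram", "ash", "gaussian")) {
    mode <- match.arg(mode)
    validObject(settings)
    rec <- locData(table)
    sp <- settings@superpixel_nm
    g <- .render_grid(rec, sp)
    img <- matrix(0, g$ny, g$nx)
    if (nrow(rec)) {
        if (mode == "histogram") {
            img <- .loc_hist(rec$x_nm, rec$y_nm, g$x0, g$y0, g$nx, g$ny, sp)
        } else if (mode == "ash") {
            s <- settings@shifts
            for (i in 0:(s - 1)) for (j in 0:(s - 1))
                img <- img + .loc_hist(rec$x_nm, rec$y_nm,
                                       g$x0 - i * sp / s, g$y0 - j * sp / s,
                                       g$nx, g$ny, sp)
            img <- img / s^2
        } else {
            ## pad the grid so splats near the data extent keep their mass
            sig_max <- max(settings@gaussian_sigma_nm,
                           if (settings@gaussian_sigma_mode == "uncertainty")
                               max(rec$uncertainty_xy_nm, 0, na.rm = TRUE)
                           else 0)
            pad <- ceiling(4 * sig_max / sp)
            g$x0 <- g$x0 - pad * sp; g$y0 <- g$y0 - pad * sp
            g$nx <- g$nx + 2L * pad; g$ny <- g$ny + 2L * pad
            img <- matrix(0, g$ny, g$nx)
            cx <- g$x0 + (seq_len(g$nx) - 0.5) * sp
            cy <- g$y0 + (seq_len(g$ny) - 0.5) * sp
            for (i in seq_len(nrow(rec))) {
                sig <- if (settings@gaussian_sigma_mode == "uncertainty" &&
                           is.finite(rec$uncertainty_xy_nm[i]))
                    rec$uncertainty_xy_nm[i] else settings@gaussian_sigma_nm
                sig <- max(sig, sp / 4)
                wx <- stats::dnorm(cx, rec$x_nm[i], sig) * sp
                wy <- stats::dnorm(cy, rec$y_nm[i], sig) * sp
                img <- img + outer(wy, wx)
            }
        }
    }
    list(image = img, origin = c(x_nm = g$x0, y_nm = g$y0),
         superpixel_nm = sp)
}

## Colour ramp for z projections: returns n x 3 RGB in [0, 1].
.z_colormap <- function(name, n = 256L) {
    cols <- switch(name,
        rainbow = grDevices::rainbow(n, start = 0.7, end = 0),  # blue -> red
        grDevices::hcl.colors(n, "viridis"))
    t(grDevices::col2rgb(cols)) / 255
}

#' Render a z colour-coded 2D projection of a 3D table
#'
#' Intensity per super-pixel is the (average shifted histogram)
#' localization count; colour encodes the mean z of the pixel's records,
#' mapped linearly over \code{z_color_range_nm} (clamped at the ends).
#' Pixels with no records are black.
#'
#' @param table a 3D \linkS4class{LocalizationTable}.
#' @param settings a \linkS4class{RenderSettings}.
#' @return list with \code{image} (ny x nx x 3 RGB array in [0, 1]),
#'   \code{origin} and \code{superpixel_nm}.
#' @export
renderZProjection <- function(table, settings = renderSettings()) {
    if (locDim(table) != 3L)
        .stop2("modeError", "z projection requires a 3D table")
    rec <- locData(table)
    sp <- settings@superpixel_nm
    g <- .render_grid(rec, sp)
    intensity <- renderImage(table, settings, "ash")$image
    zsum <- matrix(0, g$ny, g$nx); zcnt <- matrix(0, g$ny, g$nx)
    if (nrow(rec)) {
        ix <- pmin(pmax(floor((rec$x_nm - g$x0) / sp) + 1, 1), g$nx)
        iy <- pmin(pmax(floor((rec$y_nm - g$y0) / sp) + 1, 1), g$ny)
        for (i in seq_len(nrow(rec))) {
            zsum[iy[i], ix[i]] <- zsum[iy[i], ix[i]] + rec$z_nm[i]
            zcnt[iy[i], ix[i]] <- zcnt[iy[i], ix[i]] + 1
        }
    }
    cmap <- .z_colormap(settings@colormap)
    zr <- settings@z_color_range_nm
    frac <- (zsum / pmax(zcnt, 1) - zr[1]) / (zr[2] - zr[1])
    frac <- pmin(pmax(frac, 0), 1)
    ci <- matrix(as.integer(round(frac * (nrow(cmap) - 1))) + 1L,
                 g$ny, g$nx)
    bright <- intensity / max(intensity, 1e-12)
    img <- array(0, c(g$ny, g$nx, 3))
    occupied <- zcnt > 0
    for (ch in 1:3) {
        plane <- matrix(cmap[ci, ch], g$ny, g$nx) * bright
        plane[!occupied] <- 0
        img[, , ch] <- plane
    }
    list(image = img, origin = c(x_nm = g$x0, y_nm = g$y0),
         superpixel_nm = sp)
}

#' Write a rendered image to disk
#'
#' Writes a 32-bit float TIFF of the intensity data plus an 8-bit PNG
#' preview (intensity gamma-stretched for display; RGB arrays written
#' as-is).
#'
#' @param rendered result of \code{\link{renderImage}} or
#'   \code{\link{renderZProjection}}.
#' @param base_path output path without extension.
#' @return character vector of the written paths, invisibly.
#' @export
writeRendered <- function(rendered, base_path) {
    img <- rendered$image
    tif <- paste0(base_path, ".tif")
    png_path <- paste0(base_path, ".png")
    if (length(dim(img)) == 2) {
        tiff::writeTIFF(img / max(img, 1e-12), tif, bits.per.sample = 32L,
                        compression = "none")
        disp <- (img / max(img, 1e-12))^0.5   # gamma stretch for preview
        png::writePNG(disp, png_path)
    } else {
        tiff::writeTIFF(img, tif, bits.per.sample = 32L,
                        compression = "none")
        png::writePNG(img, png_path)
    }
    invisible(c(tif, png_path))
}
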