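#' @include AllClasses.R simulate.R
NULL

#' Fit astigmatism defocus curves from bead fits
#'
#' Least-squares fit of the defocus model
#' \eqn{\sigma(z) = \sigma_0\sqrt{1 + ((z - c)/d)^2}} to each axis of a
#' bead z-stack summary (already-fitted width-vs-z triplets).  The
#' calibration's validity range is the data range; per-axis residual RMS
#' values are attached as attribute \code{residual_rms_nm}.
#'
#' @param bead_fits data.frame with columns z_nm, sigma_x_nm, sigma_y_nm.
#' @param engine_tag "gaussian" or "phasor" (which estimator produced the
#'   widths).
#' @return An \linkS4class{AstigCalibration}.
#' @export
fitCalibration <- function(bead_fits, engine_tag = "gaussian") {
    need <- c("z_nm", "sigma_x_nm", "sigma_y_nm")
    if (!all(need %in% names(bead_fits)))
        .stop2("schemaError", paste0("bead_fits needs columns: ",
                                     paste(need, collapse = ", ")))
    z <- bead_fits$z_nm
    if (length(unique(z)) < 7)
        .stop2("insufficientData",
               "need >= 7 distinct z positions spanning both foci")
    fit_axis <- function(sig) {
        if (stats::sd(sig) / mean(sig) < 1e-3)
            .stop2("degenerateCalibration",
                   "widths do not vary with z on this axis")
        df <- data.frame(z = z, s = sig)
        rng <- diff(range(z))
        c0 <- z[which.min(sig)]
        ## a perfectly centred start can present nlsLM with a numerically
        ## singular initial gradient; fall back to perturbed starts
        starts <- list(
            list(s0 = min(sig), c = c0, d = rng / 2),
            list(s0 = min(sig) * 0.95, c = c0 + rng / 20, d = rng / 2.5),
            list(s0 = min(sig) * 1.05, c = c0 - rng / 20, d = rng / 1.5))
        fit <- NULL
        for (start in starts) {
            fit <- tryCatch(
                minpack.lm::nlsLM(s ~ s0 * sqrt(1 + ((z - c) / d)^2),
                                  data = df, start = start,
                                  lower = c(1e-3, -Inf, 1e-3),
                                  control = minpack.lm::nls.lm.control(
                                      maxiter = 200)),
                error = function(e) NULL)
            if (!is.null(fit)) break
        }
        if (is.null(fit))
            .stop2("degenerateCalibration",
                   "defocus model could not be fitted on this axis")
        p <- stats::coef(fit)
        list(sigma0 = unname(p["s0"]), c = unname(p["c"]),
             d = abs(unname(p["d"])),
             rms = sqrt(mean(stats::resid(fit)^2)))
    }
    fx <- fit_axis(bead_fits$sigma_x_nm)
    fy <- fit_axis(bead_fits$sigma_y_nm)
    if (abs(fx$c - fy$c) < 5)
        .stop2("degenerateCalibration",
               "focal offsets c_x and c_y coincide; no astigmatism to invert")
    cal <- astigCalibration(fx$sigma0, fx$c, fx$d, fy$sigma0, fy$c, fy$d,
                            z_min_nm = min(z), z_max_nm = max(z),
                            engine_tag = engine_tag)
    ## width-difference curve must be monotonic over the validity range,
    ## otherwise z lookup is ambiguous
    zz <- seq(cal@z_min_nm, cal@z_max_nm, length.out = 201)
    s <- .astig_sigmas(cal, zz)
    dd <- diff(s$x - s$y)
    if (!(all(dd > 0) || all(dd < 0)))
        .stop2("degenerateCalibration",
               "sigma_x(z) - sigma_y(z) is not monotonic on the data range")
    attr(cal, "residual_rms_nm") <- c(x = fx$rms, y = fy$rms)
    cal
}

#' Look up z from astigmatic widths
#'
#' Minimizes \eqn{(\sqrt{\sigma_x} - \sqrt{\sigma_{x,cal}(z)})^2 +
#' (\sqrt{\sigma_y} - \sqrt{\sigma_{y,cal}(z)})^2} over the calibration's
#' validity range on a dense 1 nm grid, then refines the minimum with a
#' local parabola.  Out-of-range widths clamp to the boundary (with a
#' large residual).  Vectorized over records.
#'
#' @param sigma_x_nm,sigma_y_nm fitted widths (nm), equal length.
#' @param cal an \linkS4class{AstigCalibration}.
#' @return list with numeric vectors \code{z_nm} and \code{residual}.
#' @export
zLookup <- function(sigma_x_nm, sigma_y_nm, cal) {
    stopifnot(length(sigma_x_nm) == length(sigma_y_nm))
    if (any(sigma_x_nm <= 0) || any(sigma_y_nm <= 0))
        .stop2("domainError", "widths must be positive")
    zz <- seq(cal@z_min_nm, cal@z_max_nm, by = 1)
    s <- .astig_sigmas(cal, zz)
    sqx <- sqrt(s$x); sqy <- sqrt(s$y)
    n <- length(sigma_x_nm)
    z_out <- res_out <- numeric(n)
    dist_at <- function(z, rx, ry) {
        sc <- .astig_sigmas(cal, z)
        (rx - sqrt(sc$x))^2 + (ry - sqrt(sc$y))^2
    }
    chunk <- 2000L
    for (lo in seq(1L, n, by = chunk)) {
        hi <- min(lo + chunk - 1L, n)
        rx <- sqrt(sigma_x_nm[lo:hi]); ry <- sqrt(sigma_y_nm[lo:hi])
        D <- outer(sqx, rx, "-")^2 + outer(sqy, ry, "-")^2
        g <- max.col(-t(D), ties.method = "first")
        for (i in seq_along(g)) {
            gi <- g[i]
            if (gi > 1 && gi < length(zz)) {
                d0 <- D[gi - 1, i]; d1 <- D[gi, i]; d2 <- D[gi + 1, i]
                den <- d0 - 2 * d1 + d2
                dz <- if (den > 0) 0.5 * (d0 - d2) / den else 0
                dz <- max(min(dz, 0.5), -0.5)
            } else dz <- 0
            zst <- zz[gi] + dz
            z_out[lo + i - 1L] <- zst
            res_out[lo + i - 1L] <- dist_at(zst, rx[i], ry[i])
        }
    }
    list(z_nm = z_out, residual = res_out)
}

#' Axial uncertainty from the calibration slope
#'
#' Propagates the lateral width uncertainty through the calibration:
#' \eqn{\Delta z = \Delta\sqrt{\sigma} / |d\sigma_{diff}/dz|} at the
#' looked-up z, with \eqn{\sigma_{diff}(z) = \sqrt{\sigma_{x,cal}} -
#' \sqrt{\sigma_{y,cal}}} and \eqn{\Delta\sqrt{\sigma} \approx
#' \Delta x / (2\sqrt{\bar\sigma})}.  Capped at 1000 nm; NA when the
#' lateral uncertainty is NA (phasor fits).
#'
#' @param sigma_x_nm,sigma_y_nm fitted widths (nm).
#' @param uncertainty_xy_nm lateral (Thompson) uncertainty (nm).
#' @param z_nm looked-up axial position (nm).
#' @param cal an \linkS4class{AstigCalibration}.
#' @return axial uncertainty (nm), vectorized.
#' @export
zUncertainty <- function(sigma_x_nm, sigma_y_nm, uncertainty_xy_nm, z_nm,
                         cal) {
    dsq <- function(z, s0, c, d) {
        sig <- .defocus_sigma(z, s0, c, d)
        dsig <- s0 * (z - c) / d^2 / sqrt(1 + ((z - c) / d)^2)
        dsig / (2 * sqrt(sig))
    }
    slope <- dsq(z_nm, cal@sigma0_x_nm, cal@c_x_nm, cal@d_x_nm) -
             dsq(z_nm, cal@sigma0_y_nm, cal@c_y_nm, cal@d_y_nm)
    sbar <- sqrt(sigma_x_nm * sigma_y_nm)
    dsqrt <- uncertainty_xy_nm / (2 * sqrt(sbar))
    pmin(dsqrt / pmax(abs(slope), 1e-12), 1000)
}

#' Write an astigmatism calibration file
#'
#' YAML with keys axis_x/axis_y: \{sigma0_nm, c_nm, d_nm\}, z_min_nm,
#' z_max_nm, engine_tag.  Round trips exactly through
#' \code{\link{readCalibration}}.
#'
#' @param cal an \linkS4class{AstigCalibration}.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
writeCalibration <- function(cal, path) {
    yaml::write_yaml(list(
        axis_x = list(sigma0_nm = cal@sigma0_x_nm, c_nm = cal@c_x_nm,
                      d_nm = cal@d_x_nm),
        axis_y = list(sigma0_nm = cal@sigma0_y_nm, c_nm = cal@c_y_nm,
                      d_nm = cal@d_y_nm),
        z_min_nm = cal@z_min_nm, z_max_nm = cal@z_max_nm,
        engine_tag = cal@engine_tag),
        path, precision = 17)
    invisible(path)
}

#' Read an astigmatism calibration file
#'
#' @param path YAML path from \code{\link{writeCalibration}}.
#' @return An \linkS4class{AstigCalibration}.
#' @export
readCalibration <- function(path) {
    if (!file.exists(path)) .stop2("ioError", paste0("no such file: ", path))
    y <- yaml::read_yaml(path)
    need_axis <- c("sigma0_nm", "c_nm", "d_nm")
    for (ax in c("axis_x", "axis_y")) {
        if (is.null(y[[ax]]))
            .stop2("schemaError", paste0("calibration file missing ", ax))
        miss <- setdiff(need_axis, names(y[[ax]]))
        if (length(miss))
            .stop2("schemaError",
                   paste0("calibration ", ax, " missing field(s): ",
                          paste(miss, collapse = ", ")))
    }
    for (k in c("z_min_nm", "z_max_nm", "engine_tag"))
        if (is.null(y[[k]]))
            .stop2("schemaError", paste0("calibration file missing ", k))
    astigCalibration(y$axis_x$sigma0_nm, y$axis_x$c_nm, y$axis_x$d_nm,
                     y$axis_y$sigma0_nm, y$axis_y$c_nm, y$axis_y$d_nm,
                     y$z_min_nm, y$z_max_nm, y$engine_tag)
}
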