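#' @include AllClasses.R
NULL

## Per-pixel integral of a 1D Gaussian over pixel j (edges (j-1)*a .. j*a).
## mu, sigma in nm; returns the vector over j = 1..n.
.int_gauss_axis <- function(n, a, mu, sigma) {
    edges <- (0:n) * a
    p <- stats::pnorm((edges - mu) / sigma)
    p[-1] - p[-(n + 1)]
}

## Defocus curve sigma(z) = sigma0 * sqrt(1 + ((z - c)/d)^2).
.defocus_sigma <- function(z, sigma0, c, d) sigma0 * sqrt(1 + ((z - c) / d)^2)

.astig_sigmas <- function(cal, z)
    list(x = .defocus_sigma(z, cal@sigma0_x_nm, cal@c_x_nm, cal@d_x_nm),
         y = .defocus_sigma(z, cal@sigma0_y_nm, cal@c_y_nm, cal@d_y_nm))

## Emitter placement.  All modes keep emitters `margin_px` pixels away from
## the field border so detection ROIs fit.
.place_emitters <- function(config, margin_px = 5) {
    w_nm <- config@width * config@camera@pixel_size_nm
    h_nm <- config@height * config@camera@pixel_size_nm
    m_nm <- margin_px * config@camera@pixel_size_nm
    n <- config@n_emitters
    if (n == 0L)
        return(matrix(numeric(0), 0, 3,
                      dimnames = list(NULL, c("x_nm", "y_nm", "z_nm"))))
    xy <- switch(config@structure,
        uniform = cbind(stats::runif(n, m_nm, w_nm - m_nm),
                        stats::runif(n, m_nm, h_nm - m_nm)),
        grid = {
            k <- ceiling(sqrt(n))
            gx <- seq(m_nm, w_nm - m_nm, length.out = k)
            gy <- seq(m_nm, h_nm - m_nm, length.out = k)
            g <- as.matrix(expand.grid(gx, gy))[seq_len(n), , drop = FALSE]
            unname(g)
        },
        filaments = .filament_points(n, w_nm, h_nm, m_nm))
    z <- if (diff(config@z_range_nm) != 0)
        stats::runif(n, config@z_range_nm[1], config@z_range_nm[2])
    else rep(0, n)
    out <- cbind(xy, z)
    colnames(out) <- c("x_nm", "y_nm", "z_nm")
    out
}

## 3-8 random quadratic Bezier curves spanning the field; candidate points
## at ~15 nm arc-length spacing with 10 nm isotropic jitter, then an evenly
## spaced subset of size n (microtubule-like structures).
.filament_points <- function(n, w_nm, h_nm, m_nm,
                             spacing_nm = 15, jitter_nm = 10) {
    n_fil <- sample(3:8, 1)
    pts <- list()
    for (f in seq_len(n_fil)) {
        p0 <- c(stats::runif(1, m_nm, w_nm - m_nm),
                stats::runif(1, m_nm, h_nm - m_nm))
        p2 <- c(stats::runif(1, m_nm, w_nm - m_nm),
                stats::runif(1, m_nm, h_nm - m_nm))
        p1 <- (p0 + p2) / 2 +
            stats::runif(2, -1, 1) * c(w_nm, h_nm) / 4
        tt <- seq(0, 1, length.out = 512)
        bx <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
        by <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
        arc <- c(0, cumsum(sqrt(diff(bx)^2 + diff(by)^2)))
        s <- seq(0, arc[length(arc)], by = spacing_nm)
        px <- stats::approx(arc, bx, s)$y
        py <- stats::approx(arc, by, s)$y
        pts[[f]] <- cbind(px, py)
    }
    all <- do.call(rbind, pts)
    all <- all + matrix(stats::rnorm(length(all), 0, jitter_nm), ncol = 2)
    all[, 1] <- pmin(pmax(all[, 1], m_nm), w_nm - m_nm)
    all[, 2] <- pmin(pmax(all[, 2], m_nm), h_nm - m_nm)
    if (nrow(all) >= n) {
        idx <- unique(round(seq(1, nrow(all), length.out = n)))
        while (length(idx) < n) idx <- c(idx, sample(nrow(all), 1))
        all[idx[seq_len(n)], , drop = FALSE]
    } else {
        extra <- all[sample(nrow(all), n - nrow(all), replace = TRUE), ,
                     drop = FALSE] +
            matrix(stats::rnorm(2 * (n - nrow(all)), 0, jitter_nm), ncol = 2)
        rbind(all, extra)
    }
}

#' Generate simulated blinking/bleaching ground truth
#'
#' Emitters are placed according to the configured structure.  Independently
#' each frame, every unbleached emitter switches ON with probability
#' \code{p_on}; after an ON event it permanently bleaches with probability
#' \code{p_bleach}.  The expected ON-event count per frame therefore decays
#' geometrically with per-frame rate \code{p_on * p_bleach}.  Photons per
#' event are lognormal with mean \code{photons_mean} and standard deviation
#' \code{photons_sd}.  Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GroundTruth}.
#' @examples
#' truth <- generateGroundTruth(simulationConfig(n_emitters = 50L, seed = 3L))
#' truth
#' @export
generateGroundTruth <- function(config) {
    validObject(config)
    set.seed(config@seed)
    emitters <- .place_emitters(config)
    n <- nrow(emitters)
    s2 <- log(1 + (config@photons_sd / config@photons_mean)^2)
    mu_ln <- log(config@photons_mean) - s2 / 2
    alive <- rep(TRUE, n)
    ev_frame <- ev_emitter <- list()
    for (k in seq_len(config@n_frames)) {
        if (!any(alive)) break
        on <- which(alive & stats::runif(n) < config@p_on)
        if (length(on)) {
            ev_frame[[k]] <- rep(k, length(on))
            ev_emitter[[k]] <- on
            if (config@p_bleach > 0) {
                bleached <- on[stats::runif(length(on)) < config@p_bleach]
                alive[bleached] <- FALSE
            }
        }
    }
    frame <- unlist(ev_frame); emitter <- unlist(ev_emitter)
    if (is.null(frame)) frame <- integer(0)
    if (is.null(emitter)) emitter <- integer(0)
    photons <- if (length(frame))
        stats::rlnorm(length(frame), mu_ln, sqrt(s2)) else numeric(0)
    drift <- cbind(dx_nm = (seq_len(config@n_frames) - 1) *
                       config@drift_nm_per_frame[1],
                   dy_nm = (seq_len(config@n_frames) - 1) *
                       config@drift_nm_per_frame[2])
    new("GroundTruth", emitters = emitters,
        events = data.frame(frame = as.integer(frame),
                            emitter = as.integer(emitter),
                            photons = photons),
        drift = drift, n_frames = config@n_frames)
}

## Expected photon image of one frame (background + integrated Gaussian
## per event), in photons.
.expected_frame <- function(truth, config, k) {
    a <- config@camera@pixel_size_nm
    mu <- matrix(config@background_photons, config@height, config@width)
    ev <- truth@events[truth@events$frame == k, , drop = FALSE]
    if (!nrow(ev)) return(mu)
    for (i in seq_len(nrow(ev))) {
        e <- truth@emitters[ev$emitter[i], ]
        x <- e[1] + truth@drift[k, 1]
        y <- e[2] + truth@drift[k, 2]
        if (!is.null(config@astig)) {
            s <- .astig_sigmas(config@astig, e[3])
            sx <- s$x; sy <- s$y
        } else sx <- sy <- config@psf_sigma_nm
        ex <- .int_gauss_axis(config@width, a, x, sx)
        ey <- .int_gauss_axis(config@height, a, y, sy)
        mu <- mu + ev$photons[i] * outer(ey, ex)
    }
    mu
}

#' Render a simulated dSTORM movie
#'
#' Per frame, each ON event is rendered as an integrated 2D Gaussian PSF
#' (error-function pixel integrals) at the emitter position shifted by the
#' cumulative drift, with width \code{psf_sigma_nm} (2D) or the astigmatic
#' \code{sigma_x(z)}, \code{sigma_y(z)} curves (3D).  The expected photon
#' image plus background passes through Poisson shot noise and Gaussian
#' read noise, then through the camera gain and baseline to uint16 counts.
#' Writes the movie TIFF (with camera sidecar), the ground-truth CSV of
#' as-imaged event positions, and (3D) the generative calibration file.
#'
#' @param truth a \linkS4class{GroundTruth} from
#'   \code{\link{generateGroundTruth}}.
#' @param config the same \linkS4class{SimulationConfig}.
#' @param out_path output movie path (TIFF).
#' @return list with elements \code{movie}, \code{truth_csv} and
#'   \code{calibration} (NULL for 2D).
#' @export
renderMovie <- function(truth, config, out_path) {
    validObject(truth)
    if (diff(config@z_range_nm) != 0 && is.null(config@astig))
        .stop2("configError",
               "3D simulation (non-zero z_range_nm) requires config@astig")
    set.seed(bitwXor(config@seed, 787878L))
    cam <- config@camera
    frames <- vector("list", config@n_frames)
    for (k in seq_len(config@n_frames)) {
        mu <- .expected_frame(truth, config, k)
        photons <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
        if (config@read_noise_e > 0)
            photons <- photons + matrix(
                stats::rnorm(length(mu), 0, config@read_noise_e),
                nrow(mu), ncol(mu))
        frames[[k]] <- photons / cam@photons_per_adu + cam@baseline_adu
    }
    writeMovie(frames, out_path, cam)
    ## ground truth CSV: as-imaged (drift-shifted) positions
    ev <- truth@events
    base <- sub("\\.ome\\.tiff?$|\\.tiff?$", "", out_path, ignore.case = TRUE)
    truth_csv <- paste0(base, ".truth.csv")
    x <- truth@emitters[ev$emitter, 1] + truth@drift[ev$frame, 1]
    y <- truth@emitters[ev$emitter, 2] + truth@drift[ev$frame, 2]
    z <- truth@emitters[ev$emitter, 3]
    lines <- c('"frame","emitter","x [nm]","y [nm]","z [nm]","photons"',
               if (nrow(ev)) paste(ev$frame, ev$emitter, .fmt_num(x),
                                   .fmt_num(y), .fmt_num(z),
                                   .fmt_num(ev$photons), sep = ","))
    con <- file(truth_csv, open = "wb"); writeLines(lines, con); close(con)
    cal_path <- NULL
    if (!is.null(config@astig)) {
        cal_path <- paste0(base, ".calibration.yaml")
        writeCalibration(config@astig, cal_path)
    }
    list(movie = out_path, truth_csv = truth_csv, calibration = cal_path)
}

#' Read a simulator ground-truth CSV
#'
#' @param path the \code{.truth.csv} written by \code{\link{renderMovie}}.
#' @return data.frame with columns frame, emitter, x_nm, y_nm, z_nm,
#'   photons (positions as imaged, i.e. including drift).
#' @export
readGroundTruth <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    stats::setNames(df, c("frame", "emitter", "x_nm", "y_nm", "z_nm",
                          "photons"))
}

#' Match localizations against ground-truth events
#'
#' For every ground-truth ON event (optionally restricted to events
#' isolated from same-frame neighbours), finds the nearest localization in
#' the same frame within \code{radius_nm}.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param truth data.frame from \code{\link{readGroundTruth}} (or a
#'   \linkS4class{GroundTruth}, converted with drift applied).
#' @param radius_nm match radius.
#' @param min_separation_nm drop events with a same-frame neighbour closer
#'   than this (0 keeps all).
#' @return data.frame, one row per considered event, with the true and
#'   fitted positions, the lateral error \code{dist_nm} and a
#'   \code{matched} flag.
#' @export
matchLocalizations <- function(table, truth, radius_nm = 50,
                               min_separation_nm = 0) {
    if (is(truth, "GroundTruth")) {
        ev <- truth@events
        truth <- data.frame(
            frame = ev$frame, emitter = ev$emitter,
            x_nm = truth@emitters[ev$emitter, 1] + truth@drift[ev$frame, 1],
            y_nm = truth@emitters[ev$emitter, 2] + truth@drift[ev$frame, 2],
            z_nm = truth@emitters[ev$emitter, 3], photons = ev$photons)
    }
    rec <- locData(table)
    if (min_separation_nm > 0 && nrow(truth) > 1) {
        keep <- rep(TRUE, nrow(truth))
        for (f in unique(truth$frame)) {
            i <- which(truth$frame == f)
            if (length(i) < 2) next
            d <- as.matrix(stats::dist(truth[i, c("x_nm", "y_nm")]))
            diag(d) <- Inf
            keep[i[apply(d, 1, min) < min_separation_nm]] <- FALSE
        }
        truth <- truth[keep, , drop = FALSE]
    }
    n <- nrow(truth)
    out <- cbind(truth,
                 x_fit = NA_real_, y_fit = NA_real_, z_fit = NA_real_,
                 intensity_fit = NA_real_, dist_nm = NA_real_,
                 matched = FALSE)
    for (f in unique(truth$frame)) {
        ti <- which(truth$frame == f)
        ri <- which(rec$frame == f)
        if (!length(ri)) next
        for (i in ti) {
            d2 <- (rec$x_nm[ri] - truth$x_nm[i])^2 +
                  (rec$y_nm[ri] - truth$y_nm[i])^2
            j <- which.min(d2)
            if (sqrt(d2[j]) <= radius_nm) {
                out$x_fit[i] <- rec$x_nm[ri[j]]
                out$y_fit[i] <- rec$y_nm[ri[j]]
                if ("z_nm" %in% names(rec)) out$z_fit[i] <- rec$z_nm[ri[j]]
                out$intensity_fit[i] <- rec$intensity_photons[ri[j]]
                out$dist_nm[i] <- sqrt(d2[j])
                out$matched[i] <- TRUE
            }
        }
    }
    rownames(out) <- NULL
    out
}
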