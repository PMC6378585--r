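#' @include AllClasses.R localize.R
NULL

.add_prov <- function(table, line) {
    table@provenance <- c(table@provenance, line)
    table
}

.keep_rows <- function(table, keep, step) {
    before <- nrow(table@records)
    rec <- table@records[keep, , drop = FALSE]
    rec$id <- seq_len(nrow(rec))
    rownames(rec) <- NULL
    out <- localizationTable(rec, dim = table@dim,
                             provenance = table@provenance)
    .add_prov(out, sprintf("%s: kept %d of %d", step, nrow(rec), before))
}

#' Apply the automated postprocessing filter chain
#'
#' Steps run in the configured order.  \code{minphot} removes unphysical
#' fits with fewer than \code{min_intensity_photons} photons (boundary
#' kept); \code{zunc} removes 3D records whose axial uncertainty exceeds
#' \code{zunc_max_nm} (boundary kept; records without an axial uncertainty,
#' e.g. phasor fits, are kept; ignored for 2D tables); \code{sigma} keeps
#' widths inside the intercentile range computed on the table as it stands
#' when the step runs; \code{drift} estimates and subtracts lateral drift;
#' \code{merge} combines consecutive-frame repeat localizations.  Each
#' step appends a provenance line with before/after counts.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param config a \linkS4class{PostprocessConfig}.
#' @param pixel_size_nm camera pixel size (needed by drift and merge).
#' @param drift_plot_path optional PNG path for the drift summary graph.
#' @return the filtered \linkS4class{LocalizationTable}.
#' @export
applyFilterChain <- function(table, config = postprocessConfig(),
                             pixel_size_nm = 100, drift_plot_path = NULL) {
    validObject(config)
    for (step in config@steps) {
        rec <- table@records
        table <- switch(step,
            minphot = .keep_rows(
                table, rec$intensity_photons >= config@min_intensity_photons,
                "minphot"),
            zunc = {
                if (table@dim == 2L)
                    .add_prov(table, "zunc: skipped (2D table)")
                else .keep_rows(
                    table, is.na(rec$uncertainty_z_nm) |
                        rec$uncertainty_z_nm <= config@zunc_max_nm, "zunc")
            },
            sigma = {
                if (nrow(rec) == 0) .add_prov(table, "sigma: kept 0 of 0")
                else {
                    lo <- .percentile(rec$sigma_nm, config@sigma_lo_centile)
                    hi <- .percentile(rec$sigma_nm, config@sigma_hi_centile)
                    .keep_rows(table,
                               rec$sigma_nm >= lo & rec$sigma_nm <= hi,
                               sprintf("sigma [%g, %g] nm", lo, hi))
                }
            },
            drift = {
                traj <- estimateDrift(table, n_bins = config@drift_bins,
                                      magnification =
                                          config@drift_magnification,
                                      pixel_size_nm = pixel_size_nm,
                                      plot_path = drift_plot_path)
                applyDriftCorrection(table, traj)
            },
            merge = mergeConsecutive(table,
                                     radius_nm = config@merge_radius_nm,
                                     max_gap_frames =
                                         config@merge_max_gap_frames,
                                     pixel_size_nm = pixel_size_nm),
            .stop2("configError", paste0("unknown step token: ", step)))
    }
    table
}

## 2D count histogram of localizations on a super-pixel grid.
.loc_hist <- function(x, y, x0, y0, nx, ny, sp) {
    ix <- floor((x - x0) / sp) + 1
    iy <- floor((y - y0) / sp) + 1
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    h <- matrix(0, ny, nx)
    if (any(ok)) {
        t <- table(factor(iy[ok], levels = seq_len(ny)),
                   factor(ix[ok], levels = seq_len(nx)))
        h <- matrix(as.numeric(t), ny, nx)
    }
    h
}

## Paraboloid peak refinement on the 3x3 neighbourhood of (r, c) of
## correlation matrix C (wrapped indexing): least-squares quadratic
## f = a + bx + cy + dx^2 + ey^2 + fxy, peak at the stationary point.
.paraboloid_peak <- function(C, r, c) {
    n <- nrow(C); m <- ncol(C)
    off <- -1:1
    idx <- expand.grid(dy = off, dx = off)
    v <- mapply(function(dy, dx)
        C[((r - 1 + dy) %% n) + 1, ((c - 1 + dx) %% m) + 1],
        idx$dy, idx$dx)
    X <- cbind(1, idx$dx, idx$dy, idx$dx^2, idx$dy^2, idx$dx * idx$dy)
    beta <- solve(crossprod(X), crossprod(X, v))
    H <- matrix(c(2 * beta[4], beta[6], beta[6], 2 * beta[5]), 2, 2)
    g <- c(beta[2], beta[3])
    shift <- tryCatch(-solve(H, g), error = function(e) c(0, 0))
    shift <- pmax(pmin(shift, 1), -1)   # refinement stays inside the 3x3
    c(dx = unname(shift[1]), dy = unname(shift[2]))
}

## Circularly wrapped 2D Gaussian kernel (unit mass), for FFT-domain
## smoothing of correlation surfaces.
.wrapped_gauss <- function(n, m, sigma) {
    kr <- stats::dnorm(pmin(0:(n - 1), n - (0:(n - 1))), sd = sigma)
    kc <- stats::dnorm(pmin(0:(m - 1), m - (0:(m - 1))), sd = sigma)
    K <- outer(kr, kc)
    K / sum(K)
}

## Circular FFT cross-correlation peak: displacement of histogram Hk
## relative to H1, in super-pixels (dx along columns, dy along rows).
## Drift within a temporal bin smears the correlation peak into a broad
## plateau whose discrete argmax jitters by whole super-pixels under
## sampling noise; smoothing the correlation surface (circular Gaussian,
## sigma = 2 super-pixels) before peak finding stabilizes it.
.xcorr_shift <- function(H1, Hk, smooth_px = 2) {
    F <- stats::fft(H1) * Conj(stats::fft(Hk))
    if (smooth_px > 0)
        F <- F * stats::fft(.wrapped_gauss(nrow(H1), ncol(H1), smooth_px))
    C <- Re(stats::fft(F, inverse = TRUE))
    p <- which(C == max(C), arr.ind = TRUE)[1, ]
    sub <- .paraboloid_peak(C, p[1], p[2])
    wrap <- function(i, n) { i <- i - 1; if (i > n / 2) i - n else i }
    c(dx = -(unname(wrap(p[2], ncol(C))) + unname(sub["dx"])),
      dy = -(unname(wrap(p[1], nrow(C))) + unname(sub["dy"])))
}

#' Estimate lateral drift by redundant cross-correlation
#'
#' Frames are split into \code{n_bins} equal contiguous temporal bins;
#' each bin is rendered as a 2D histogram at super-pixel size
#' \code{pixel_size_nm / magnification} and cross-correlated against the
#' first bin via FFT, with sub-pixel peak refinement by a paraboloid fit
#' on the 3x3 neighbourhood of the correlation maximum.  Bin-centre
#' displacements are interpolated linearly to per-frame values (end
#' segments extrapolated linearly) and re-referenced so frame 1 is (0, 0).
#'
#' @param table a \linkS4class{LocalizationTable} spanning >= n_bins
#'   distinct frames.
#' @param n_bins number of temporal bins (default 5).
#' @param magnification histogram super-resolution factor (default 5).
#' @param pixel_size_nm camera pixel size (nm).
#' @param plot_path optional PNG path for a drift summary graph.
#' @return A \linkS4class{DriftTrajectory} covering frames 1..max(frame).
#' @export
estimateDrift <- function(table, n_bins = 5L, magnification = 5L,
                          pixel_size_nm = 100, plot_path = NULL) {
    rec <- locData(table)
    if (length(unique(rec$frame)) < n_bins)
        .stop2("driftError",
               sprintf("table spans fewer than %d distinct frames", n_bins))
    f_max <- max(rec$frame)
    sp <- pixel_size_nm / magnification
    edges <- seq(0, f_max, length.out = n_bins + 1)
    bin_of <- pmin(pmax(findInterval(rec$frame, edges, left.open = TRUE),
                        1L), n_bins)
    counts <- tabulate(bin_of, n_bins)
    if (any(counts < 10))
        .stop2("driftError", sprintf(
            "bin %d has only %d localizations (< 10); use fewer bins",
            which(counts < 10)[1], counts[which(counts < 10)[1]]))
    x0 <- min(rec$x_nm); y0 <- min(rec$y_nm)
    nx <- max(8L, ceiling((max(rec$x_nm) - x0) / sp) + 1L)
    ny <- max(8L, ceiling((max(rec$y_nm) - y0) / sp) + 1L)
    H1 <- .loc_hist(rec$x_nm[bin_of == 1], rec$y_nm[bin_of == 1],
                    x0, y0, nx, ny, sp)
    centres <- (edges[-1] + edges[-(n_bins + 1)]) / 2
    dx <- dy <- numeric(n_bins)
    for (k in 2:n_bins) {
        Hk <- .loc_hist(rec$x_nm[bin_of == k], rec$y_nm[bin_of == k],
                        x0, y0, nx, ny, sp)
        s <- .xcorr_shift(H1, Hk)
        dx[k] <- s["dx"] * sp
        dy[k] <- s["dy"] * sp
    }
    interp <- function(v) {
        out <- stats::approx(centres, v, seq_len(f_max), rule = 2)$y
        ## linear extrapolation on the end segments
        lo <- which(seq_len(f_max) < centres[1])
        hi <- which(seq_len(f_max) > centres[n_bins])
        if (length(lo)) {
            sl <- (v[2] - v[1]) / (centres[2] - centres[1])
            out[lo] <- v[1] + (lo - centres[1]) * sl
        }
        if (length(hi)) {
            sl <- (v[n_bins] - v[n_bins - 1]) /
                (centres[n_bins] - centres[n_bins - 1])
            out[hi] <- v[n_bins] + (hi - centres[n_bins]) * sl
        }
        out
    }
    fx <- interp(dx); fy <- interp(dy)
    fx <- fx - fx[1]; fy <- fy - fy[1]    # frame 1 references the trajectory
    traj <- new("DriftTrajectory", frames = seq_len(f_max),
                dx_nm = fx, dy_nm = fy)
    if (!is.null(plot_path))
        tryCatch({
            grDevices::png(plot_path, width = 700, height = 500)
            graphics::plot(traj@frames, traj@dx_nm, type = "l", col = "blue",
                           xlab = "frame", ylab = "drift [nm]",
                           main = "Lateral drift correction",
                           ylim = range(c(traj@dx_nm, traj@dy_nm)))
            graphics::lines(traj@frames, traj@dy_nm, col = "red")
            graphics::points(centres, dx - fx[1], col = "blue", pch = 19)
            graphics::points(centres, dy - fy[1], col = "red", pch = 19)
            graphics::legend("topleft", c("x", "y"), col = c("blue", "red"),
                             lty = 1)
            grDevices::dev.off()
        }, error = function(e) try(grDevices::dev.off(), silent = TRUE))
    traj
}

#' Subtract a drift trajectory from a localization table
#'
#' Positions are reduced by the displacement of their frame.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param traj a \linkS4class{DriftTrajectory} covering the table's frame
#'   range.
#' @return the corrected \linkS4class{LocalizationTable}.
#' @export
applyDriftCorrection <- function(table, traj) {
    rec <- table@records
    if (nrow(rec) && max(rec$frame) > max(traj@frames))
        .stop2("driftError", "trajectory does not cover the frame range")
    rec$x_nm <- rec$x_nm - traj@dx_nm[rec$frame]
    rec$y_nm <- rec$y_nm - traj@dy_nm[rec$frame]
    out <- localizationTable(rec, dim = table@dim,
                             provenance = table@provenance)
    .add_prov(out, sprintf(
        "drift: corrected %d records over %d frames (max |d| = %.1f nm)",
        nrow(rec), length(traj@frames),
        max(abs(c(traj@dx_nm, traj@dy_nm)), 0)))
}

#' Merge localizations of one emitter in consecutive frames
#'
#' Greedy chaining in frame order: a record joins an open chain when its
#' frame exceeds the chain's last frame by at least 1 and at most
#' \code{1 + max_gap_frames} and it lies within \code{radius_nm} of the
#' chain's photon-weighted centroid (nearest chain wins).  Records in the
#' same frame are never merged.  A merged record keeps the first frame,
#' photon-weighted positions and widths, summed intensity, and a lateral
#' uncertainty recomputed from the merged photon count via the Thompson
#' formula.
#'
#' @param table a \linkS4class{LocalizationTable} sorted by frame.
#' @param radius_nm capture radius around the chain centroid.
#' @param max_gap_frames allowed number of skipped frames inside a chain.
#' @param pixel_size_nm camera pixel size (Thompson recomputation).
#' @return the merged \linkS4class{LocalizationTable}.
#' @export
mergeConsecutive <- function(table, radius_nm = 50, max_gap_frames = 0L,
                             pixel_size_nm = 100) {
    rec <- table@records
    if (is.unsorted(rec$frame))
        .stop2("mergeError", "table must be sorted by frame")
    n <- nrow(rec)
    if (n == 0) return(.add_prov(table, "merge: kept 0 of 0"))
    three_d <- table@dim == 3L
    chains <- list()       # open chains
    done <- list()         # closed chains
    gap <- 1L + as.integer(max_gap_frames)
    for (i in seq_len(n)) {
        f <- rec$frame[i]
        ## retire chains that can no longer accept records
        if (length(chains)) {
            expired <- vapply(chains, function(ch) ch$last_frame < f - gap,
                              logical(1))
            done <- c(done, chains[expired])
            chains <- chains[!expired]
        }
        best <- 0L; best_d <- Inf
        for (j in seq_along(chains)) {
            ch <- chains[[j]]
            if (ch$last_frame >= f) next          # same frame: never merged
            d <- sqrt((rec$x_nm[i] - ch$x)^2 + (rec$y_nm[i] - ch$y)^2)
            if (d <= radius_nm && d < best_d) { best <- j; best_d <- d }
        }
        if (best > 0L) {
            ch <- chains[[best]]
            ch$members <- c(ch$members, i)
            w_old <- ch$N; w_new <- rec$intensity_photons[i]
            wt <- w_old + w_new
            ch$x <- (ch$x * w_old + rec$x_nm[i] * w_new) / wt
            ch$y <- (ch$y * w_old + rec$y_nm[i] * w_new) / wt
            ch$N <- wt
            ch$last_frame <- f
            chains[[best]] <- ch
        } else {
            chains[[length(chains) + 1L]] <- list(
                members = i, x = rec$x_nm[i], y = rec$y_nm[i],
                N = rec$intensity_photons[i], first_frame = f,
                last_frame = f)
        }
    }
    done <- c(done, chains)
    first <- vapply(done, `[[`, integer(1), "first_frame")
    first_member <- vapply(done, function(ch) ch$members[1], integer(1))
    done <- done[order(first, first_member)]
    wmean <- function(v, m, w) sum(v[m] * w) / sum(w)
    out <- do.call(rbind, lapply(done, function(ch) {
        m <- ch$members
        w <- rec$intensity_photons[m]
        N <- sum(w)
        sig <- wmean(rec$sigma_nm, m, w)
        bkg <- wmean(rec$bkgstd_photons, m, w)
        unc <- if (all(is.na(rec$uncertainty_xy_nm[m]))) NA_real_
               else thompsonUncertainty(sig, pixel_size_nm, N, bkg)
        row <- data.frame(
            frame = ch$first_frame, x_nm = ch$x, y_nm = ch$y,
            sigma_nm = sig, intensity_photons = N,
            offset_photons = wmean(rec$offset_photons, m, w),
            bkgstd_photons = bkg, uncertainty_xy_nm = unc)
        if (three_d) {
            row$z_nm <- wmean(rec$z_nm, m, w)
            row$sigma1_nm <- wmean(rec$sigma1_nm, m, w)
            row$sigma2_nm <- wmean(rec$sigma2_nm, m, w)
            ## axial precision improves ~ 1/sqrt(N) like the lateral one
            uz <- rec$uncertainty_z_nm[m]
            row$uncertainty_z_nm <- if (all(is.na(uz))) NA_real_
                else wmean(ifelse(is.na(uz), mean(uz, na.rm = TRUE), uz),
                           seq_along(m), w) * sqrt(max(w) / N)
        }
        row
    }))
    out$id <- seq_len(nrow(out))
    res <- localizationTable(out, dim = table@dim,
                             provenance = table@provenance)
    .add_prov(res, sprintf("merge: %d records -> %d (radius %g nm, gap %d)",
                           n, nrow(out), radius_nm,
                           as.integer(max_gap_frames)))
}
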