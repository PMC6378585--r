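#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Integrated-Gaussian PSF model on a square photon patch.
##
## Patch pixel (i, j) (1-based row/col) spans [j-1, j] x [i-1, i] in patch
## pixel units; the model is
##     mu_ij = N * Ey_i(y0, sy) * Ex_j(x0, sx) + b
## with E the error-function integral of a unit Gaussian over the pixel.
## ---------------------------------------------------------------------------

## E and dE/dmu, dE/dsigma for one axis (vectorized over pixels).
.axis_terms <- function(W, mu, sigma) {
    lo <- (seq_len(W) - 1 - mu) / sigma
    hi <- (seq_len(W) - mu) / sigma
    E <- stats::pnorm(hi) - stats::pnorm(lo)
    dlo <- stats::dnorm(lo); dhi <- stats::dnorm(hi)
    list(E = E,
         dmu = (dlo - dhi) / sigma,
         dsigma = (dlo * lo - dhi * hi) / sigma)
}

#' Initial parameter estimate for a photon patch
#'
#' Background is the patch minimum; N is the background-subtracted sum;
#' the position is the intensity centroid of the background-subtracted
#' patch; sigma starts at a configured PSF prior.
#'
#' @param roi photon patch (square matrix, side >= 5).
#' @param sigma_prior_px initial width guess in pixels (default 1.3).
#' @return list with x_px, y_px (patch pixel-edge coordinates), sigma_px,
#'   N_photons, b_photons.
#' @export
estimateInitial <- function(roi, sigma_prior_px = 1.3) {
    if (nrow(roi) < 5L || ncol(roi) < 5L)
        .stop2("degenerateInput", "patch side must be >= 5")
    b <- min(roi)
    resid <- roi - b
    N <- sum(resid)
    if (!is.finite(N) || N <= 0)
        .stop2("degenerateInput",
               "patch has no intensity above its minimum (constant patch?)")
    cx <- seq_len(ncol(roi)) - 0.5
    cy <- seq_len(nrow(roi)) - 0.5
    list(x_px = sum(colSums(resid) * cx) / N,
         y_px = sum(rowSums(resid) * cy) / N,
         sigma_px = sigma_prior_px, N_photons = N, b_photons = b)
}

## Model + Jacobian at theta.  theta: (x0, y0, sx[, sy], N, b); symmetric
## fits carry a single sigma.
.psf_model <- function(theta, W, H, elliptical) {
    x0 <- theta[1]; y0 <- theta[2]
    if (elliptical) { sx <- theta[3]; sy <- theta[4]
                      N <- theta[5]; b <- theta[6] }
    else            { sx <- sy <- theta[3]; N <- theta[4]; b <- theta[5] }
    ax <- .axis_terms(W, x0, sx)
    ay <- .axis_terms(H, y0, sy)
    mu <- N * outer(ay$E, ax$E) + b
    J <- cbind(
        x0 = as.vector(N * outer(ay$E, ax$dmu)),
        y0 = as.vector(N * outer(ay$dmu, ax$E)),
        if (elliptical)
            cbind(sx = as.vector(N * outer(ay$E, ax$dsigma)),
                  sy = as.vector(N * outer(ay$dsigma, ax$E)))
        else
            cbind(s = as.vector(N * (outer(ay$E, ax$dsigma) +
                                     outer(ay$dsigma, ax$E)))),
        N = as.vector(outer(ay$E, ax$E)),
        b = 1)
    list(mu = as.vector(mu), J = J)
}

.nwls_obj <- function(y, mu, w) sum(w * (y - mu)^2)
.mle_obj <- function(y, mu) { mu <- pmax(mu, 1e-6); sum(mu - y * log(mu)) }

## Background noise estimate: SD of the one-pixel border ring of the patch
## (dominated by background away from the spot centre).
.border_sd <- function(roi) {
    n <- nrow(roi); m <- ncol(roi)
    ring <- c(roi[1, ], roi[n, ], roi[2:(n - 1), 1], roi[2:(n - 1), m])
    stats::sd(ring)
}

.diverged <- function(theta, W, H, elliptical) {
    x0 <- theta[1]; y0 <- theta[2]
    sig <- if (elliptical) theta[3:4] else theta[3]
    N <- if (elliptical) theta[5] else theta[4]
    x0 < 0 || x0 > W || y0 < 0 || y0 > H ||
        any(sig < 0.3) || any(sig > 10) || N <= 0
}

#' Fit an integrated Gaussian PSF to a photon patch
#'
#' Iterative sub-pixel localization with a Levenberg-Marquardt-damped
#' Gauss-Newton (NWLS) or Fisher-scoring (Poisson MLE) iteration.  NWLS
#' minimizes \eqn{\sum_i w_i (y_i - \mu_i)^2} with \eqn{w_i = 1/\max(y_i, 1)};
#' MLE minimizes \eqn{\sum_i (\mu_i - y_i \ln \mu_i)} with \eqn{\mu_i}
#' floored at \eqn{10^{-6}}.  Iteration stops when the largest relative
#' parameter change falls below \eqn{10^{-6}} or after 50 iterations.
#' Divergence (position leaving the patch, width outside [0.3, 10] px, or
#' non-positive N) yields a non-converged result, never an error.
#'
#' @param roi photon patch (square matrix).
#' @param init initial parameters from \code{\link{estimateInitial}}.
#' @param engine "nwls" or "mle".
#' @param elliptical fit separate x/y widths (astigmatic 3D) when TRUE.
#' @return list (fit result): x_px, y_px, sigma_x_px, sigma_y_px,
#'   N_photons, b_photons, bkgstd_photons, converged, n_iter, engine.
#' @export
fitGaussian <- function(roi, init = estimateInitial(roi),
                        engine = c("nwls", "mle"), elliptical = FALSE) {
    engine <- match.arg(engine)
    W <- ncol(roi); H <- nrow(roi)
    y <- as.vector(roi)
    theta <- if (elliptical)
        c(init$x_px, init$y_px, init$sigma_px, init$sigma_px,
          init$N_photons, init$b_photons)
    else
        c(init$x_px, init$y_px, init$sigma_px, init$N_photons,
          init$b_photons)
    fail <- function(n_iter) list(
        x_px = theta[1], y_px = theta[2],
        sigma_x_px = if (elliptical) theta[3] else theta[3],
        sigma_y_px = if (elliptical) theta[4] else theta[3],
        N_photons = if (elliptical) theta[5] else theta[4],
        b_photons = theta[length(theta)],
        bkgstd_photons = .border_sd(roi), converged = FALSE,
        n_iter = n_iter, engine = engine)
    if (!all(is.finite(theta)) || init$N_photons <= 0) return(fail(0L))
    w_nwls <- 1 / pmax(y, 1)
    obj <- function(th) {
        m <- .psf_model(th, W, H, elliptical)$mu
        if (engine == "nwls") .nwls_obj(y, m, w_nwls) else .mle_obj(y, m)
    }
    f <- obj(theta)
    lambda <- 1e-3
    converged <- FALSE
    iter <- 0L
    while (iter < 50L) {
        iter <- iter + 1L
        mdl <- .psf_model(theta, W, H, elliptical)
        mu <- mdl$mu; J <- mdl$J
        if (engine == "nwls") {
            wt <- w_nwls
            g <- crossprod(J, wt * (y - mu))          # descent direction
        } else {
            mu_f <- pmax(mu, 1e-6)
            wt <- 1 / mu_f                            # Fisher weights
            g <- crossprod(J, (y / mu_f - 1))
        }
        A <- crossprod(J, wt * J)
        dA <- diag(A); dA[dA <= 0] <- 1e-12
        accepted <- FALSE
        repeat {
            step <- tryCatch(
                solve(A + lambda * diag(dA, nrow = length(dA)), g),
                error = function(e) NULL)
            if (!is.null(step) && all(is.finite(step))) {
                cand <- theta + as.vector(step)
                f_new <- if (all(is.finite(cand))) obj(cand) else Inf
                if (is.finite(f_new) && f_new <= f) {
                    rel <- max(abs(step) / pmax(abs(theta), 1e-6))
                    theta <- cand; f <- f_new
                    lambda <- max(lambda / 10, 1e-12)
                    accepted <- TRUE
                    if (rel < 1e-6) converged <- TRUE
                    break
                }
            }
            lambda <- lambda * 10
            if (lambda > 1e8) {
                ## no admissible downhill step left: we are at (or stuck
                ## near) a minimum -- converged if the attempted step was
                ## negligible
                if (!is.null(step) && all(is.finite(step)) &&
                    max(abs(step) / pmax(abs(theta), 1e-6)) < 1e-6)
                    converged <- TRUE
                break
            }
        }
        if (converged || !accepted) break
        if (.diverged(theta, W, H, elliptical)) return(fail(iter))
    }
    if (.diverged(theta, W, H, elliptical)) return(fail(iter))
    if (elliptical) {
        sx <- theta[3]; sy <- theta[4]; N <- theta[5]; b <- theta[6]
    } else {
        sx <- sy <- theta[3]; N <- theta[4]; b <- theta[5]
    }
    list(x_px = theta[1], y_px = theta[2], sigma_x_px = sx, sigma_y_px = sy,
         N_photons = N, b_photons = b, bkgstd_photons = .border_sd(roi),
         converged = converged, n_iter = iter, engine = engine)
}

#' Phasor-based localization (non-iterative)
#'
#' After subtracting the patch minimum, the first Fourier coefficients
#' along each axis are computed; the position follows from their phase
#' and Gaussian width proxies from their magnitude:
#' \eqn{\hat\sigma = (W/\pi)\sqrt{\ln(\Sigma I/|P|)/2}}.  Always
#' "converged" with \code{n_iter = 0}.
#'
#' @param roi square photon patch, side >= 5.
#' @return fit-result list as in \code{\link{fitGaussian}}, with
#'   \code{engine = "phasor"}.
#' @export
fitPhasor <- function(roi) {
    W <- ncol(roi); H <- nrow(roi)
    if (W != H || W < 5L) .stop2("degenerateInput",
                                 "phasor needs a square patch, side >= 5")
    b <- min(roi)
    y <- roi - b
    S <- sum(y)
    if (S <= 0) .stop2("degenerateInput", "patch has zero total intensity")
    u_col <- exp(-2i * pi * (seq_len(W) - 1) / W)   # along x (columns)
    u_row <- exp(-2i * pi * (seq_len(H) - 1) / H)   # along y (rows)
    Px <- sum(colSums(y) * u_col)
    Py <- sum(rowSums(y) * u_row)
    if (Mod(Px) > S || Mod(Py) > S || Mod(Px) == 0 || Mod(Py) == 0)
        .stop2("degenerateInput", "phasor magnitude incompatible with a spot")
    loc <- function(P, n) {
        phi <- Arg(P)
        if (phi > 0) phi <- phi - 2 * pi
        -phi * n / (2 * pi)
    }
    ## |P| == S (a single bright pixel) gives a zero-width proxy
    sig <- function(P, n) (n / pi) * sqrt(max(log(S / Mod(P)), 0) / 2)
    list(x_px = loc(Px, W) + 0.5, y_px = loc(Py, H) + 0.5,
         sigma_x_px = sig(Px, W), sigma_y_px = sig(Py, H),
         N_photons = S, b_photons = b, bkgstd_photons = .border_sd(roi),
         converged = TRUE, n_iter = 0L, engine = "phasor")
}

#' Thompson lateral localization precision
#'
#' \deqn{\Delta x^2 = \frac{\sigma^2 + a^2/12}{N}
#'       + \frac{8\pi\sigma^4 b^2}{a^2 N^2}}
#' with \eqn{\sigma} the (geometric-mean) PSF width in nm, \eqn{a} the
#' pixel size, \eqn{N} the photon count and \eqn{b} the background
#' standard deviation in photons.
#'
#' @param sigma_nm PSF width (geometric mean for elliptical fits), nm.
#' @param pixel_size_nm camera pixel size, nm.
#' @param N_photons photon count (> 0).
#' @param bkgstd_photons background standard deviation, photons.
#' @return lateral precision in nm.
#' @examples
#' thompsonUncertainty(130, 100, 1000, 10)  # ~9.46 nm
#' @export
thompsonUncertainty <- function(sigma_nm, pixel_size_nm, N_photons,
                                bkgstd_photons) {
    if (any(N_photons <= 0)) .stop2("domainError", "N_photons must be > 0")
    a <- pixel_size_nm
    sqrt((sigma_nm^2 + a^2 / 12) / N_photons +
         8 * pi * sigma_nm^4 * bkgstd_photons^2 / (a^2 * N_photons^2))
}

#' Lateral uncertainty of a fit result
#'
#' Thompson precision for Gaussian fits; \code{NA} for phasor fits (no
#' uncertainty output is defined for the phasor estimator).
#'
#' @param fit a fit-result list from \code{\link{fitGaussian}} or
#'   \code{\link{fitPhasor}}.
#' @param camera a \linkS4class{CameraModel}.
#' @return uncertainty in nm, or NA for phasor fits.
#' @export
localizationUncertainty <- function(fit, camera) {
    if (identical(fit$engine, "phasor")) return(NA_real_)
    if (fit$N_photons <= 0) .stop2("domainError", "N_photons must be > 0")
    a <- camera@pixel_size_nm
    sigma_nm <- sqrt(fit$sigma_x_px * fit$sigma_y_px) * a
    thompsonUncertainty(sigma_nm, a, fit$N_photons, fit$bkgstd_photons)
}

#' Localize emitters in a strided frame subset
#'
#' For every frame in the subset: detect candidates, extract photon ROIs,
#' fit each candidate with the chosen engine, discard non-converged fits
#' and convert to physical units.  With a calibration, fitting is
#' elliptical and each record gets z from \code{\link{zLookup}} plus an
#' axial uncertainty from the calibration slope.  Records carry true frame
#' numbers and are ordered (frame, detection order).
#'
#' @param handle a \linkS4class{MovieHandle}.
#' @param start first frame of the subset (worker index).
#' @param stride frame step (number of workers).
#' @param engine "nwls", "mle" or "phasor".
#' @param detection a \linkS4class{DetectionParams}.
#' @param calibration optional \linkS4class{AstigCalibration}; its presence
#'   selects the 3D pipeline.
#' @param log_path optional run-log file appended to per frame batch.
#' @return A \linkS4class{LocalizationTable}.
#' @export
localizeFrames <- function(handle, start = 1L, stride = 1L,
                           engine = c("nwls", "mle", "phasor"),
                           detection = detectionParams(),
                           calibration = NULL, log_path = NULL) {
    engine <- match.arg(engine)
    three_d <- !is.null(calibration)
    if (three_d && detection@roi_radius_px < 4L)
        detection <- detectionParams(detection@dog_sigma1_px,
                                     detection@dog_sigma2_px,
                                     detection@k_threshold, 4L)
    cam <- handle@camera
    a <- cam@pixel_size_nm
    frames <- frameSequence(handle, start, stride)
    rows <- list()
    n_fit <- 0L
    for (k in frames) {
        px <- readFrame(handle, k)
        cand <- detectSpots(px, detection)
        if (!nrow(cand)) next
        for (i in seq_len(nrow(cand))) {
            roi <- extractRoi(px, cand$row_px[i], cand$col_px[i],
                              detection@roi_radius_px, cam)
            fit <- tryCatch({
                if (engine == "phasor") fitPhasor(roi$patch)
                else fitGaussian(roi$patch, estimateInitial(roi$patch),
                                 engine = engine, elliptical = three_d)
            }, degenerateInput = function(e) NULL)
            if (is.null(fit) || !fit$converged) next
            n_fit <- n_fit + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                frame = k,
                x_nm = roi$origin_x_nm + fit$x_px * a,
                y_nm = roi$origin_y_nm + fit$y_px * a,
                sigma_nm = sqrt(fit$sigma_x_px * fit$sigma_y_px) * a,
                sigma1_nm = fit$sigma_x_px * a,
                sigma2_nm = fit$sigma_y_px * a,
                intensity_photons = fit$N_photons,
                offset_photons = fit$b_photons,
                bkgstd_photons = fit$bkgstd_photons,
                uncertainty_xy_nm = localizationUncertainty(fit, cam))
        }
    }
    rec <- if (length(rows)) do.call(rbind, rows) else
        data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                   sigma_nm = numeric(0), sigma1_nm = numeric(0),
                   sigma2_nm = numeric(0), intensity_photons = numeric(0),
                   offset_photons = numeric(0), bkgstd_photons = numeric(0),
                   uncertainty_xy_nm = numeric(0))
    if (three_d && nrow(rec)) {
        zl <- zLookup(rec$sigma1_nm, rec$sigma2_nm, calibration)
        rec$z_nm <- zl$z_nm
        rec$uncertainty_z_nm <- zUncertainty(rec$sigma1_nm, rec$sigma2_nm,
                                             rec$uncertainty_xy_nm,
                                             zl$z_nm, calibration)
    } else if (three_d) {
        rec$z_nm <- numeric(0); rec$uncertainty_z_nm <- numeric(0)
    }
    if (!three_d) { rec$sigma1_nm <- NULL; rec$sigma2_nm <- NULL }
    rec$id <- seq_len(nrow(rec))
    prov <- sprintf(
        "localize: engine=%s frames start=%d stride=%d (%d frames), %d localizations",
        engine, start, stride, length(frames), nrow(rec))
    .log_line(log_path, prov)
    localizationTable(rec, dim = if (three_d) 3L else 2L, provenance = prov)
}
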