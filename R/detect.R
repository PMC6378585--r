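#' @include AllClasses.R
NULL

## Separable Gaussian convolution with replicated edges, exact (direct,
## not FFT) so detection is bit-reproducible.
.gauss_kernel_1d <- function(sigma) {
    h <- max(1L, as.integer(ceiling(3 * sigma)))
    k <- stats::dnorm(seq(-h, h), sd = sigma)
    k / sum(k)
}

.conv_sep <- function(img, k) {
    h <- (length(k) - 1L) %/% 2L
    n <- nrow(img); m <- ncol(img)
    pad <- img[c(rep(1L, h), seq_len(n), rep(n, h)),
               c(rep(1L, h), seq_len(m), rep(m, h)), drop = FALSE]
    Kr <- matrix(0, n, n + 2L * h)
    for (i in seq_len(n)) Kr[i, i:(i + 2L * h)] <- k
    Km <- matrix(0, m, m + 2L * h)
    for (j in seq_len(m)) Km[j, j:(j + 2L * h)] <- k
    Kr %*% pad %*% t(Km)
}

## Difference-of-Gaussians band-pass.
.dog_filter <- function(img, sigma1, sigma2)
    .conv_sep(img, .gauss_kernel_1d(sigma1)) -
    .conv_sep(img, .gauss_kernel_1d(sigma2))

#' Detect spot candidates in one frame
#'
#' The frame is band-pass filtered with a difference of Gaussians; spot
#' candidates are strict 8-neighbourhood local maxima of the filtered image
#' whose value exceeds \code{k_threshold} times the robust standard
#' deviation (1.4826 x median absolute deviation) of the filtered image.
#' Ties between equal neighbours keep the first candidate in row-major
#' order.  Candidates within \code{roi_radius_px} of the border are
#' discarded; output is ordered row-major.
#'
#' @param frame_pixels numeric matrix of raw counts (ADU).
#' @param params a \linkS4class{DetectionParams}.
#' @return data.frame with columns row_px, col_px (1-based pixel indices)
#'   and peak_value (filtered-image value); zero rows when nothing is found.
#' @export
detectSpots <- function(frame_pixels, params = detectionParams()) {
    validObject(params)
    rad <- params@roi_radius_px
    n <- nrow(frame_pixels); m <- ncol(frame_pixels)
    if (n < 2L * rad + 1L || m < 2L * rad + 1L)
        .stop2("boundsError", "frame smaller than one ROI")
    filt <- .dog_filter(frame_pixels, params@dog_sigma1_px,
                        params@dog_sigma2_px)
    ## mad() includes the 1.4826 consistency constant; the floor keeps
    ## numerically flat (noise-free) frames from passing at threshold zero
    thr <- params@k_threshold *
        max(stats::mad(filt), 1e-9 * max(abs(filt)), .Machine$double.eps)
    is_max <- filt > thr
    if (any(is_max)) {
        for (di in -1:1) for (dj in -1:1) {
            if (di == 0L && dj == 0L) next
            nb <- matrix(-Inf, n, m)
            src_r <- seq_len(n) + di; src_c <- seq_len(m) + dj
            ok_r <- src_r >= 1L & src_r <= n; ok_c <- src_c >= 1L & src_c <= m
            nb[ok_r, ok_c] <- filt[src_r[ok_r], src_c[ok_c]]
            later <- di > 0L || (di == 0L && dj > 0L)
            is_max <- is_max & (if (later) filt >= nb else filt > nb)
        }
    }
    ## border policy: candidate must be at least roi_radius from every edge
    keep <- matrix(FALSE, n, m)
    keep[(rad + 1L):(n - rad), (rad + 1L):(m - rad)] <- TRUE
    idx <- which(is_max & keep, arr.ind = TRUE)
    if (!nrow(idx))
        return(data.frame(row_px = integer(0), col_px = integer(0),
                          peak_value = numeric(0)))
    ord <- order(idx[, 1], idx[, 2])  # row-major
    idx <- idx[ord, , drop = FALSE]
    data.frame(row_px = as.integer(idx[, 1]), col_px = as.integer(idx[, 2]),
               peak_value = filt[idx])
}

#' Extract a photon-valued ROI around a candidate
#'
#' Returns the square patch of side \code{2 * radius + 1} centred on the
#' candidate, converted from counts to photons as
#' \code{(ADU - baseline_adu) * photons_per_adu}, clipped below at zero,
#' together with the nm coordinates of the patch's (0,0) pixel corner.
#'
#' @param frame_pixels numeric matrix of raw counts.
#' @param row_px,col_px candidate position (1-based pixel indices).
#' @param radius integer half-width.
#' @param camera a \linkS4class{CameraModel}.
#' @return list with elements \code{patch} (photon matrix), and
#'   \code{origin_x_nm}, \code{origin_y_nm}.
#' @export
extractRoi <- function(frame_pixels, row_px, col_px, radius, camera) {
    n <- nrow(frame_pixels); m <- ncol(frame_pixels)
    if (row_px - radius < 1L || row_px + radius > n ||
        col_px - radius < 1L || col_px + radius > m)
        .stop2("boundsError",
               sprintf("ROI around (%d, %d) exceeds the frame", row_px,
                       col_px))
    patch <- frame_pixels[(row_px - radius):(row_px + radius),
                          (col_px - radius):(col_px + radius)]
    patch <- pmax((patch - camera@baseline_adu) * camera@photons_per_adu, 0)
    a <- camera@pixel_size_nm
    list(patch = patch,
         origin_x_nm = (col_px - radius - 1) * a,
         origin_y_nm = (row_px - radius - 1) * a)
}
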