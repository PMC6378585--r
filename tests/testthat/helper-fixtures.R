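## Shared fixtures, built in code (no stored data).  Expensive artefacts
## (rendered movies) are memoized per test run.

.fixtures <- new.env(parent = emptyenv())

## Noiseless integrated-Gaussian photon patch in pixel units (pixel size 1):
## the generative oracle for the fitting engines.
ts_patch <- function(W, x0, y0, sx, sy = sx, N = 1000, b = 0) {
    ex <- pnorm((1:W) - x0, sd = sx) - pnorm((0:(W - 1)) - x0, sd = sx)
    ey <- pnorm((1:W) - y0, sd = sy) - pnorm((0:(W - 1)) - y0, sd = sy)
    N * outer(ey, ex) + b
}

## Standard astigmatic calibration used across 3D tests.
ts_cal <- function()
    astigCalibration(130, 150, 400, 132, -150, 420,
                     z_min_nm = -500, z_max_nm = 500)

## Simulated movie on disk, memoized by label.
ts_movie <- function(label, config) {
    key <- paste0("movie_", label)
    if (is.null(.fixtures[[key]])) {
        dir <- file.path(tempdir(), paste0("fix_", label))
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        truth <- generateGroundTruth(config)
        paths <- renderMovie(truth, config,
                             file.path(dir, paste0(label, ".ome.tif")))
        .fixtures[[key]] <- list(config = config, truth = truth,
                                 paths = paths)
    }
    .fixtures[[key]]
}

## Small 2D localization table built directly (filter-contract tests).
ts_table <- function(n = 10, frame = seq_len(n), x = seq_len(n) * 100,
                     y = rev(seq_len(n)) * 100, sigma = rep(130, n),
                     intensity = rep(1000, n), unc_z = NULL) {
    rec <- data.frame(id = seq_len(n), frame = frame, x_nm = x, y_nm = y,
                      sigma_nm = sigma, intensity_photons = intensity,
                      offset_photons = 5, bkgstd_photons = 3,
                      uncertainty_xy_nm = 10)
    if (!is.null(unc_z)) {
        rec$z_nm <- 0
        rec$sigma1_nm <- sigma
        rec$sigma2_nm <- sigma
        rec$uncertainty_z_nm <- unc_z
    }
    localizationTable(rec)
}

## Localization table synthesized from ground truth (as-imaged positions
## plus isotropic localization noise) -- stands in for the localization
## stage where only downstream behaviour is under test.
ts_table_from_truth <- function(truth, jitter_nm = 5, seed = 99L) {
    set.seed(seed)
    ev <- truth@events
    n <- nrow(ev)
    rec <- data.frame(
        id = seq_len(n), frame = ev$frame,
        x_nm = truth@emitters[ev$emitter, 1] + truth@drift[ev$frame, 1] +
            rnorm(n, 0, jitter_nm),
        y_nm = truth@emitters[ev$emitter, 2] + truth@drift[ev$frame, 2] +
            rnorm(n, 0, jitter_nm),
        sigma_nm = 130, intensity_photons = ev$photons,
        offset_photons = 5, bkgstd_photons = 3, uncertainty_xy_nm = 10)
    rec <- rec[order(rec$frame), ]
    rec$id <- seq_len(n)
    localizationTable(rec)
}

## Number of distinct ON events (maximal runs of consecutive ON frames
## per emitter), enumerated from ground truth -- oracle for the
## consecutive-frame merge.
ts_count_on_runs <- function(truth) {
    ev <- truth@events
    sum(vapply(split(ev$frame, ev$emitter), function(f) {
        f <- sort(f)
        sum(diff(c(-10L, f)) > 1L)
    }, numeric(1)))
}
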