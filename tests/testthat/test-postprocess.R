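test_that("the minimum-photon filter keeps the one-photon boundary", {
    tab <- ts_table(3, intensity = c(0.2, 1.0, 3.5))
    out <- applyFilterChain(tab, postprocessConfig(steps = "minphot"))
    expect_identical(nLocalizations(out), 2L)
    expect_setequal(locData(out)$intensity_photons, c(1.0, 3.5))
    expect_match(tail(provenance(out), 1), "kept 2 of 3")
})

test_that("the z-uncertainty filter keeps the 500 nm boundary, skips 2D", {
    tab3 <- ts_table(3, unc_z = c(100, 500, 501))
    out <- applyFilterChain(tab3, postprocessConfig(steps = "zunc"))
    expect_identical(nLocalizations(out), 2L)
    expect_setequal(locData(out)$uncertainty_z_nm, c(100, 500))
    ## records with no z uncertainty (phasor) are retained
    tabNA <- ts_table(3, unc_z = c(100, NA, 600))
    expect_identical(
        nLocalizations(applyFilterChain(tabNA,
                                        postprocessConfig(steps = "zunc"))),
        2L)
    ## 2D tables pass through untouched
    tab2 <- ts_table(3)
    out2 <- applyFilterChain(tab2, postprocessConfig(steps = "zunc"))
    expect_identical(nLocalizations(out2), 3L)
    expect_match(tail(provenance(out2), 1), "skipped")
})

test_that("the intercentile sigma filter uses rank p*(n-1) interpolation", {
    ## sigma = 1..20: P10 = 2.9, P75 = 15.25, keep 3..15 -> 13 records
    tab <- ts_table(20, sigma = 1:20)
    out <- applyFilterChain(tab, postprocessConfig(steps = "sigma"))
    expect_identical(nLocalizations(out), 13L)
    expect_equal(range(locData(out)$sigma_nm), c(3, 15))
    expect_match(tail(provenance(out), 1), "\\[2.9, 15.25\\]")
    ## brute-force oracle for the percentile convention itself
    brute <- function(x, p) {
        x <- sort(x); r <- p / 100 * (length(x) - 1)
        lo <- floor(r); x[lo + 1] + (r - lo) * (x[lo + 2] - x[lo + 1])
    }
    expect_equal(parastorm:::.percentile(1:20, 10), brute(1:20, 10))
    expect_equal(parastorm:::.percentile(1:20, 75), brute(1:20, 75))
    set.seed(71)
    x <- rlnorm(37, 5, 0.3)
    for (p in c(10, 25, 75, 90))
        expect_equal(parastorm:::.percentile(x, p), brute(x, p))
})

test_that("filters remove rows without altering survivors", {
    set.seed(72)
    tab <- ts_table(50, sigma = runif(50, 80, 250),
                    intensity = runif(50, 0.5, 2000))
    out <- applyFilterChain(tab, postprocessConfig(
        steps = c("minphot", "sigma")))
    rec_in <- locData(tab); rec_out <- locData(out)
    key_in <- paste(rec_in$x_nm, rec_in$y_nm, rec_in$sigma_nm,
                    rec_in$intensity_photons)
    key_out <- paste(rec_out$x_nm, rec_out$y_nm, rec_out$sigma_nm,
                     rec_out$intensity_photons)
    expect_true(all(key_out %in% key_in))
    ## provenance counts chain consistently
    prov <- provenance(out)
    expect_length(prov, 2)
    expect_error(postprocessConfig(steps = "nonsense"), "unknown")
})

test_that("a constructed two-bin shift is recovered by cross-correlation", {
    set.seed(73)
    n <- 2000
    x <- runif(n, 500, 5900); y <- runif(n, 500, 5900)
    rec <- data.frame(id = seq_len(2 * n), frame = rep(1:2, each = n),
                      x_nm = c(x, x + 100), y_nm = c(y, y),
                      sigma_nm = 130, intensity_photons = 1000,
                      offset_photons = 5, bkgstd_photons = 3,
                      uncertainty_xy_nm = 10)
    traj <- estimateDrift(localizationTable(rec), n_bins = 2,
                          magnification = 5, pixel_size_nm = 100)
    expect_lt(abs(traj@dx_nm[2] - 100), 5)
    expect_lt(abs(traj@dy_nm[2]), 5)
    ## drift-free data: displacements below one super-pixel
    traj0 <- estimateDrift(ts_table_from_truth(generateGroundTruth(
        simulationConfig(n_frames = 50L, n_emitters = 300L, p_on = 0.2,
                         structure = "filaments", seed = 74L))),
        n_bins = 5, magnification = 5, pixel_size_nm = 100)
    expect_lt(max(abs(c(traj0@dx_nm, traj0@dy_nm))), 20)
})

test_that("drift correction subtracts the trajectory (sign convention)", {
    tab <- ts_table(1, frame = 2L)
    traj <- new("DriftTrajectory", frames = 1:2, dx_nm = c(0, 5),
                dy_nm = c(0, -5))
    out <- applyDriftCorrection(tab, traj)
    expect_equal(locData(out)$x_nm, locData(tab)$x_nm - 5)
    expect_equal(locData(out)$y_nm, locData(tab)$y_nm + 5)
    ## zero trajectory leaves the table unchanged
    z <- new("DriftTrajectory", frames = 1:2, dx_nm = c(0, 0),
             dy_nm = c(0, 0))
    expect_equal(locData(applyDriftCorrection(tab, z))$x_nm,
                 locData(tab)$x_nm)
    ## coverage is enforced
    expect_error(applyDriftCorrection(ts_table(1, frame = 9L), traj),
                 class = "driftError")
})

test_that("linear drift is recovered and correction is near-idempotent", {
    cfg <- simulationConfig(n_frames = 600L, n_emitters = 400L, p_on = 0.1,
                            structure = "filaments",
                            drift_nm_per_frame = c(2, -1), seed = 75L)
    truth <- generateGroundTruth(cfg)
    tab <- ts_table_from_truth(truth, jitter_nm = 10)
    traj <- estimateDrift(tab, n_bins = 5, magnification = 5,
                          pixel_size_nm = 100)
    frames <- seq_len(max(locData(tab)$frame))
    fit <- lm(traj@dx_nm ~ frames)
    expect_lt(abs(coef(fit)[2] - 2) / 2, 0.2)
    corrected <- applyDriftCorrection(tab, traj)
    traj2 <- estimateDrift(corrected, n_bins = 5, magnification = 5,
                           pixel_size_nm = 100)
    expect_lt(max(abs(c(traj2@dx_nm, traj2@dy_nm))), 15)
    ## a bin with too few localizations is a hard error
    expect_error(estimateDrift(ts_table(30, frame = rep(1:6, each = 5)),
                               n_bins = 6), class = "driftError")
})

test_that("consecutive-frame repeats merge into photon-weighted records", {
    rec <- data.frame(id = 1:2, frame = c(3L, 4L), x_nm = c(1000, 1010),
                      y_nm = c(2000, 2000), sigma_nm = c(130, 130),
                      intensity_photons = c(500, 600),
                      offset_photons = 5, bkgstd_photons = c(3, 3),
                      uncertainty_xy_nm = 10)
    out <- mergeConsecutive(localizationTable(rec), radius_nm = 50,
                            max_gap_frames = 0L)
    expect_identical(nLocalizations(out), 1L)
    m <- locData(out)
    expect_identical(m$frame, 3L)
    expect_equal(m$intensity_photons, 1100)
    expect_equal(m$x_nm, (1000 * 500 + 1010 * 600) / 1100)
    ## uncertainty recomputed from the merged photon count
    expect_equal(m$uncertainty_xy_nm,
                 thompsonUncertainty(130, 100, 1100, 3))
})

test_that("same-frame localizations are never merged", {
    rec <- data.frame(id = 1:2, frame = c(3L, 3L), x_nm = c(1000, 1001),
                      y_nm = c(2000, 2001), sigma_nm = 130,
                      intensity_photons = 500, offset_photons = 5,
                      bkgstd_photons = 3, uncertainty_xy_nm = 10)
    out <- mergeConsecutive(localizationTable(rec), radius_nm = 50)
    expect_identical(nLocalizations(out), 2L)
})

test_that("merged record count equals the number of distinct ON events", {
    ## p_on = 1: every emitter stays ON until it bleaches -> exactly one
    ## ON run per activated emitter
    cfg <- simulationConfig(n_frames = 60L, n_emitters = 49L, p_on = 1,
                            p_bleach = 0.3, structure = "grid", seed = 76L)
    truth <- generateGroundTruth(cfg)
    n_runs <- ts_count_on_runs(truth)
    expect_identical(n_runs, 49)   # one run each
    tab <- ts_table_from_truth(truth, jitter_nm = 5)
    merged <- mergeConsecutive(tab, radius_nm = 50, max_gap_frames = 0L)
    expect_identical(nLocalizations(merged), as.integer(n_runs))
    ## every input record lands in exactly one output record
    expect_equal(sum(locData(merged)$intensity_photons),
                 sum(locData(tab)$intensity_photons))
})
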