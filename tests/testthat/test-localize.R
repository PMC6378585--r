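test_that("initial estimates recover centroid, background and intensity", {
    roi <- ts_patch(7, 3.5, 3.5, 1.3, N = 1000, b = 5)
    init <- estimateInitial(roi)
    expect_equal(init$x_px, 3.5, tolerance = 1e-6)   # symmetric spot
    expect_equal(init$y_px, 3.5, tolerance = 1e-6)
    expect_equal(init$b_photons, min(roi))
    ## offset spot: centroid within 0.2 px of truth (tail truncation bias)
    roi2 <- ts_patch(7, 3.9, 3.5, 1.3, N = 1000)
    expect_lt(abs(estimateInitial(roi2)$x_px - 3.9), 0.2)
    ## constant patch is degenerate
    expect_error(estimateInitial(matrix(7, 7, 7)), class = "degenerateInput")
    expect_error(estimateInitial(matrix(0, 4, 4)), class = "degenerateInput")
})

test_that("both iterative engines recover noiseless spot parameters", {
    roi <- ts_patch(7, 3.2, 3.7, 1.3, N = 1000, b = 5)
    for (eng in c("nwls", "mle")) {
        fit <- fitGaussian(roi, estimateInitial(roi), engine = eng)
        expect_true(fit$converged)
        expect_lte(fit$n_iter, 50L)
        expect_lt(abs(fit$x_px - 3.2), 1e-3)
        expect_lt(abs(fit$y_px - 3.7), 1e-3)
        expect_lt(abs(fit$sigma_x_px - 1.3) / 1.3, 0.005)
        expect_lt(abs(fit$N_photons - 1000) / 1000, 0.005)
        expect_lt(abs(fit$b_photons - 5), 0.1)
        expect_identical(fit$engine, eng)
    }
})

test_that("elliptical fits recover the width ratio of astigmatic spots", {
    roi <- ts_patch(9, 4.3, 4.6, sx = 1.1, sy = 1.7, N = 2000, b = 3)
    for (eng in c("nwls", "mle")) {
        fit <- fitGaussian(roi, estimateInitial(roi), engine = eng,
                           elliptical = TRUE)
        expect_true(fit$converged)
        ratio <- fit$sigma_x_px / fit$sigma_y_px
        expect_lt(abs(ratio - 1.1 / 1.7) / (1.1 / 1.7), 0.02)
    }
})

test_that("pure-background patches yield a non-converged flag, not an error", {
    init <- list(x_px = 3.5, y_px = 3.5, sigma_px = 1.3, N_photons = 0,
                 b_photons = 7)
    fit <- fitGaussian(matrix(7, 7, 7), init, engine = "nwls")
    expect_false(fit$converged)
})

test_that("fits are deterministic for identical input", {
    set.seed(41)
    roi <- ts_patch(7, 3.4, 3.1, 1.3, N = 800, b = 10) +
        matrix(rpois(49, 10), 7, 7)
    f1 <- fitGaussian(roi, estimateInitial(roi), "mle")
    f2 <- fitGaussian(roi, estimateInitial(roi), "mle")
    expect_identical(f1, f2)
    p1 <- fitPhasor(roi); p2 <- fitPhasor(roi)
    expect_identical(p1, p2)
    expect_identical(p1$n_iter, 0L)
})

test_that("phasor localization is exact for a delta and accurate for spots", {
    ## single nonzero pixel at 0-based index (3,3): local coordinate (3,3)
    d <- matrix(0, 7, 7); d[4, 4] <- 5
    fd <- fitPhasor(d)
    expect_equal(fd$x_px - 0.5, 3, tolerance = 1e-12)
    expect_equal(fd$y_px - 0.5, 3, tolerance = 1e-12)
    ## noiseless Gaussian at 3.2 px: position within 0.05 px
    roi <- ts_patch(7, 3.2, 3.6, 1.3, N = 1000, b = 2)
    fp <- fitPhasor(roi)
    expect_lt(abs(fp$x_px - 3.2), 0.05)
    expect_lt(abs(fp$y_px - 3.6), 0.05)
    ## width proxy close to the true sigma for an in-window spot
    expect_lt(abs(fp$sigma_x_px - 1.3) / 1.3, 0.05)
    ## degenerate inputs
    expect_error(fitPhasor(matrix(3, 7, 7)), class = "degenerateInput")
    expect_error(fitPhasor(matrix(0, 3, 3)), class = "degenerateInput")
})

test_that("engines agree on noiseless spots", {
    roi <- ts_patch(7, 3.35, 3.55, 1.3, N = 1500, b = 4)
    xn <- fitGaussian(roi, estimateInitial(roi), "nwls")$x_px
    xm <- fitGaussian(roi, estimateInitial(roi), "mle")$x_px
    xp <- fitPhasor(roi)$x_px
    expect_lt(abs(xn - xm), 1e-3)
    expect_lt(abs(xp - xm), 0.05)
})

test_that("Thompson precision formula matches its closed form", {
    ## sigma 130 nm, pixel 100 nm, 1000 photons, background std 10
    expect_equal(thompsonUncertainty(130, 100, 1000, 10), 9.461234,
                 tolerance = 1e-6)
    ## b = 0, a -> 0 limit: sigma / sqrt(N)
    expect_equal(thompsonUncertainty(130, 1e-6, 1000, 0), 130 / sqrt(1000),
                 tolerance = 1e-6)
    ## doubling N with b = 0 reduces the (sigma^2 + a^2/12) term by sqrt(2)
    r <- thompsonUncertainty(130, 100, 1000, 0) /
         thompsonUncertainty(130, 100, 2000, 0)
    expect_equal(r, sqrt(2), tolerance = 1e-12)
    expect_error(thompsonUncertainty(130, 100, 0, 10), class = "domainError")
    ## phasor fits carry no uncertainty
    fp <- fitPhasor(ts_patch(7, 3.2, 3.2, 1.3, N = 1000))
    expect_true(is.na(localizationUncertainty(fp, cameraModel(100, 0.5, 0))))
})

test_that("localizeFrames produces ordered physical-unit tables", {
    fx <- ts_movie("loc", simulationConfig(
        n_frames = 20L, n_emitters = 25L, p_on = 0.15,
        structure = "uniform", seed = 103L))
    mov <- openMovie(fx$paths$movie)
    tab <- localizeFrames(mov, 1, 1, engine = "mle")
    rec <- locData(tab)
    expect_false(is.unsorted(rec$frame))
    expect_identical(rec$id, seq_len(nrow(rec)))
    expect_identical(locDim(tab), 2L)
    ## >= 95% of isolated true events matched within 50 nm
    m <- matchLocalizations(tab, fx$truth, radius_nm = 50,
                            min_separation_nm = 500)
    expect_gte(mean(m$matched), 0.95)
    ## strided subsets carry true frame numbers
    t2 <- localizeFrames(mov, 2, 4, engine = "mle")
    expect_true(all(locData(t2)$frame %in% c(2L, 6L, 10L, 14L, 18L)))
    ## determinism
    t2b <- localizeFrames(mov, 2, 4, engine = "mle")
    expect_identical(locData(t2), locData(t2b))
})

test_that("an empty movie subset yields an empty table", {
    cfg <- simulationConfig(n_frames = 3L, n_emitters = 0L,
                            background_photons = 0, read_noise_e = 0,
                            seed = 104L)
    paths <- renderMovie(generateGroundTruth(cfg), cfg,
                         file.path(tempdir(), "empty.ome.tif"))
    tab <- localizeFrames(openMovie(paths$movie), 1, 1, engine = "phasor")
    expect_identical(nLocalizations(tab), 0L)
})
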