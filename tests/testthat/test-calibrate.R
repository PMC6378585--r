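test_that("defocus curves are recovered exactly from clean samples", {
    cal0 <- ts_cal()
    z <- seq(-500, 500, by = 40)
    s <- with(list(), {
        sx <- 130 * sqrt(1 + ((z - 150) / 400)^2)
        sy <- 132 * sqrt(1 + ((z + 150) / 420)^2)
        list(x = sx, y = sy)
    })
    cal <- fitCalibration(data.frame(z_nm = z, sigma_x_nm = s$x,
                                     sigma_y_nm = s$y))
    expect_lt(abs(cal@sigma0_x_nm - 130) / 130, 0.001)
    expect_lt(abs(cal@c_x_nm - 150) / 150, 0.001)
    expect_lt(abs(cal@d_x_nm - 400) / 400, 0.001)
    expect_lt(abs(cal@c_y_nm + 150) / 150, 0.001)
    expect_equal(cal@z_min_nm, -500)
    expect_equal(cal@z_max_nm, 500)
    expect_lt(max(attr(cal, "residual_rms_nm")), 1e-6)
})

test_that("noisy bead fits report a residual RMS near the noise level", {
    set.seed(51)
    z <- seq(-500, 500, by = 25)
    sx <- 130 * sqrt(1 + ((z - 150) / 400)^2)
    sy <- 132 * sqrt(1 + ((z + 150) / 420)^2)
    noise <- 0.01
    cal <- fitCalibration(data.frame(
        z_nm = z, sigma_x_nm = sx * (1 + rnorm(length(z), 0, noise)),
        sigma_y_nm = sy * (1 + rnorm(length(z), 0, noise))))
    rms <- attr(cal, "residual_rms_nm")
    expected <- noise * mean(sx)   # ~1.5 nm
    expect_gt(min(rms), expected * 0.4)
    expect_lt(max(rms), expected * 2.5)
})

test_that("degenerate calibrations are rejected", {
    z <- seq(-500, 500, by = 100)
    ## z-independent widths
    expect_error(fitCalibration(data.frame(z_nm = z, sigma_x_nm = 130,
                                           sigma_y_nm = 132)),
                 class = "degenerateCalibration")
    ## coincident foci (no astigmatism)
    s <- 130 * sqrt(1 + (z / 400)^2)
    expect_error(fitCalibration(data.frame(z_nm = z, sigma_x_nm = s,
                                           sigma_y_nm = s * 1.01)),
                 class = "degenerateCalibration")
    ## too few points
    expect_error(fitCalibration(data.frame(z_nm = z[1:5], sigma_x_nm = s[1:5],
                                           sigma_y_nm = s[1:5])),
                 class = "insufficientData")
    ## the class itself refuses c_x == c_y
    expect_error(astigCalibration(130, 150, 400, 130, 150, 400),
                 "differ")
})

test_that("z lookup inverts the forward model across the range", {
    cal <- ts_cal()
    ## symmetric widths sit at the crossing point of the curves
    s0 <- parastorm:::.astig_sigmas(cal, 0)
    zl0 <- zLookup(mean(unlist(s0)), mean(unlist(s0)), cal)
    expect_lt(abs(zl0$z_nm), 20)
    ## forward-model round trip at z = 200 within 1 nm
    s <- parastorm:::.astig_sigmas(cal, 200)
    expect_lt(abs(zLookup(s$x, s$y, cal)$z_nm - 200), 1)
    ## property: round trip within 1 nm on a grid over the central range
    zz <- seq(-450, 450, by = 30)
    sc <- parastorm:::.astig_sigmas(cal, zz)
    back <- zLookup(sc$x, sc$y, cal)
    expect_lt(max(abs(back$z_nm - zz)), 1)
    expect_lt(max(back$residual), 1e-4)
})

test_that("a perfectly mirrored calibration maps equal widths to z = 0", {
    cal <- astigCalibration(130, 150, 400, 130, -150, 400)
    zl <- zLookup(150, 150, cal)
    expect_lt(abs(zl$z_nm), 1)
})

test_that("z lookup degrades gracefully under width noise", {
    set.seed(52)
    cal <- ts_cal()
    s <- parastorm:::.astig_sigmas(cal, 200)
    err <- replicate(50, {
        zl <- zLookup(s$x * (1 + rnorm(1, 0, 0.05)),
                      s$y * (1 + rnorm(1, 0, 0.05)), cal)
        zl$z_nm - 200
    })
    expect_lt(median(abs(err)), 40)
})

test_that("calibration files round trip exactly and validate their schema", {
    cal <- ts_cal()
    p <- file.path(tempdir(), "cal.yaml")
    writeCalibration(cal, p)
    back <- readCalibration(p)
    for (sl in c("sigma0_x_nm", "c_x_nm", "d_x_nm", "sigma0_y_nm",
                 "c_y_nm", "d_y_nm", "z_min_nm", "z_max_nm"))
        expect_identical(slot(back, sl), slot(cal, sl), info = sl)
    expect_identical(back@engine_tag, "gaussian")
    ## engine tag survives
    cal2 <- astigCalibration(120, 100, 350, 125, -120, 360,
                             engine_tag = "phasor")
    writeCalibration(cal2, p)
    expect_identical(readCalibration(p)@engine_tag, "phasor")
    ## missing field -> schema error
    y <- yaml::read_yaml(p)
    y$axis_x$d_nm <- NULL
    yaml::write_yaml(y, p)
    expect_error(readCalibration(p), "d_nm", class = "schemaError")
})

test_that("axial uncertainty propagates the width uncertainty and is capped", {
    cal <- ts_cal()
    s <- parastorm:::.astig_sigmas(cal, 150)
    dz <- zUncertainty(s$x, s$y, 10, 150, cal)
    expect_gt(dz, 0)
    expect_lt(dz, 1000)
    ## larger lateral uncertainty -> larger axial uncertainty
    expect_gt(zUncertainty(s$x, s$y, 30, 150, cal), dz)
    ## cap at 1000 nm for hopeless inputs
    expect_equal(zUncertainty(s$x, s$y, 1e6, 150, cal), 1000)
})
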