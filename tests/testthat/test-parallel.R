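test_that("interleaved plans assign frames round-robin", {
    plan <- planInterleave(13, 4)
    expect_identical(assignments(plan)[[1]], c(1L, 5L, 9L, 13L))
    expect_identical(assignments(plan)[[2]], c(2L, 6L, 10L))
    expect_identical(assignments(plan)[[3]], c(3L, 7L, 11L))
    expect_identical(assignments(plan)[[4]], c(4L, 8L, 12L))
    expect_identical(assignments(planInterleave(5, 1))[[1]], 1:5)
})

test_that("plans partition the frame range for arbitrary (n, W)", {
    set.seed(61)
    for (i in 1:20) {
        n <- sample(1:500, 1)
        W <- sample(seq_len(min(n, 16)), 1)
        plan <- planInterleave(n, W)
        frames <- unlist(assignments(plan))
        expect_identical(sort(frames), seq_len(n))
        expect_lte(diff(range(lengths(assignments(plan)))), 1L)
    }
    expect_error(planInterleave(4, 5), class = "planError")
    expect_error(planInterleave(10, 0), class = "planError")
})

test_that("merging restores frame order and reassigns ids", {
    tab <- ts_table(12, frame = c(1:6, 1:6))
    parts <- lapply(list(c(1, 3, 5), c(2, 4, 6)), function(fr) {
        rec <- locData(tab)[locData(tab)$frame %in% fr, ]
        localizationTable(rec)
    })
    merged <- mergeTables(parts)
    rec <- locData(merged)
    expect_false(is.unsorted(rec$frame))
    expect_identical(rec$id, seq_len(12L))
    expect_identical(nLocalizations(merged), 12L)
    ## merge(split(T)) == T up to id reassignment
    orig <- locData(tab)[order(locData(tab)$frame), ]
    orig$id <- seq_len(nrow(orig))
    rownames(orig) <- NULL
    expect_equal(rec, orig)
    ## single input: unchanged except ids
    single <- mergeTables(list(tab))
    expect_identical(nLocalizations(single), 12L)
    ## overlapping frame sets are rejected
    expect_error(mergeTables(list(parts[[1]], parts[[1]])),
                 class = "mergeError")
})

parallel_fx <- function() ts_movie("par", simulationConfig(
    n_frames = 40L, n_emitters = 30L, p_on = 0.12, structure = "filaments",
    seed = 105L))

test_that("merged tables are byte-identical for W in {1, 2, 4} (all engines)", {
    mov <- openMovie(parallel_fx()$paths$movie)
    for (eng in c("nwls", "phasor")) {
        md5 <- vapply(c(1L, 2L, 4L), function(W) {
            out <- file.path(tempdir(), sprintf("peq_%s_%d", eng, W))
            rep <- runParallel(mov, planInterleave(nFrames(mov), W),
                               engine = eng, output_dir = out,
                               backend = "serial")
            expect_identical(sum(rep@worker_counts),
                             nLocalizations(rep@table))
            unname(tools::md5sum(rep@merged_path))
        }, character(1))
        expect_identical(length(unique(md5)), 1L)
    }
})

test_that("the fork backend reproduces the serial result", {
    mov <- openMovie(parallel_fx()$paths$movie)
    out_s <- file.path(tempdir(), "bk_serial")
    out_f <- file.path(tempdir(), "bk_fork")
    rs <- runParallel(mov, planInterleave(40, 4), engine = "phasor",
                      output_dir = out_s, backend = "serial")
    rf <- runParallel(mov, planInterleave(40, 4), engine = "phasor",
                      output_dir = out_f, backend = "fork")
    expect_identical(unname(tools::md5sum(rs@merged_path)),
                     unname(tools::md5sum(rf@merged_path)))
    ## worker scratch layout: part/config/log per worker
    for (w in 1:4) {
        expect_true(file.exists(file.path(out_f, "workers",
                                          sprintf("part_%d.csv", w))))
        expect_true(file.exists(file.path(out_f, "workers",
                                          sprintf("config_%d.txt", w))))
        expect_true(file.exists(file.path(out_f, "workers",
                                          sprintf("log_%d.txt", w))))
    }
})

test_that("job manifests describe every worker's strided subset", {
    mov <- openMovie(parallel_fx()$paths$movie)
    dir <- file.path(tempdir(), "manifests")
    paths <- exportManifests(mov, planInterleave(40, 4), dir,
                             engine = "mle", jobs_per_node = 2L)
    expect_length(paths, 4)
    m3 <- yaml::read_yaml(file.path(dir, "worker_3.yaml"))
    expect_identical(m3$start, 3L)
    expect_identical(m3$stride, 4L)
    expect_identical(m3$engine, "mle")
    expect_identical(m3$node, 2L)
})

test_that("batch mode equals parallel mode for a single movie", {
    fx <- parallel_fx()
    res <- runBatch(fx$paths$movie, n_slots = 1L, jobs_per_node = 2L,
                    engine = "phasor", post = "minphot",
                    preview = FALSE, backend = "serial")
    expect_length(res, 1)
    expect_null(res[[1]]$error)
    direct <- runPipeline(fx$paths$movie, n_nodes = 1L, jobs_per_node = 2L,
                          engine = "phasor", post = "minphot",
                          preview = FALSE, backend = "serial")
    expect_equal(locData(res[[1]]$raw), locData(direct$raw))
    ## each movie gets its own output directory
    expect_true(dir.exists(res[[1]]$output_dir))
    expect_false(identical(res[[1]]$output_dir, direct$output_dir))
})

test_that("a failing movie does not abort the rest of a batch", {
    fx <- parallel_fx()
    res <- runBatch(c(fx$paths$movie, "/nonexistent/movie.tif"),
                    n_slots = 1L, engine = "phasor", post = "minphot",
                    preview = FALSE, backend = "serial")
    expect_null(res[[1]]$error)
    expect_false(is.null(res[[2]]$error))
})
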