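#' @include AllClasses.R localize.R io-table.R
NULL

#' Plan an interleaved frame assignment
#'
#' Worker w of W is assigned the frames \code{f} with
#' \code{(f - 1) mod W == w - 1} (round-robin).  Because emitter activity
#' decays over the acquisition, interleaving gives every worker a
#' comparable share of the localization workload, unlike a contiguous
#' block split.
#'
#' @param n_frames number of frames.
#' @param n_workers number of workers (1 <= n_workers <= n_frames).
#' @return A \linkS4class{WorkerPlan}.
#' @examples
#' planInterleave(13, 4)  # worker 1: 1, 5, 9, 13; worker 2: 2, 6, 10; ...
#' @export
planInterleave <- function(n_frames, n_workers) {
    n_frames <- as.integer(n_frames); n_workers <- as.integer(n_workers)
    if (n_workers < 1L || n_workers > n_frames)
        .stop2("planError",
               sprintf("need 1 <= n_workers (%d) <= n_frames (%d)",
                       n_workers, n_frames))
    new("WorkerPlan", n_frames = n_frames, n_workers = n_workers,
        assignments = lapply(seq_len(n_workers), function(w)
            seq.int(w, n_frames, by = n_workers)))
}

#' Merge per-worker localization tables in frame order
#'
#' Concatenates frame-disjoint worker tables and stable-sorts by frame
#' (within a frame the original order is preserved; each frame belongs to
#' exactly one worker).  Ids are reassigned 1..M and provenance lines are
#' concatenated in worker order.
#'
#' @param worker_tables list of \linkS4class{LocalizationTable}s with
#'   pairwise disjoint frame sets.
#' @return the merged \linkS4class{LocalizationTable}.
#' @export
mergeTables <- function(worker_tables) {
    stopifnot(length(worker_tables) >= 1)
    dims <- vapply(worker_tables, locDim, integer(1))
    if (length(unique(dims)) != 1)
        .stop2("mergeError", "tables mix 2D and 3D records")
    frame_sets <- lapply(worker_tables, function(t) unique(locData(t)$frame))
    all_frames <- unlist(frame_sets)
    if (anyDuplicated(all_frames))
        .stop2("mergeError",
               "worker tables have overlapping frame sets")
    rec <- do.call(rbind, lapply(worker_tables, locData))
    rec <- rec[order(rec$frame), , drop = FALSE]   # stable in R
    rec$id <- seq_len(nrow(rec))
    localizationTable(rec, dim = dims[1],
                      provenance = c(unlist(lapply(worker_tables,
                                                   provenance)),
                                     sprintf("merge: %d worker table(s), %d localizations, frame order restored",
                                             length(worker_tables),
                                             nrow(rec))))
}

## One worker: localize its strided subset and leave part_<w>.csv,
## config_<w>.txt and log_<w>.txt in the scratch directory.
.run_worker <- function(w, handle, plan, engine, detection, calibration,
                        scratch) {
    t0 <- proc.time()[["elapsed"]]
    log_w <- file.path(scratch, sprintf("log_%d.txt", w))
    tab <- localizeFrames(handle, start = w, stride = plan@n_workers,
                          engine = engine, detection = detection,
                          calibration = calibration, log_path = log_w)
    writeLocalizations(tab, file.path(scratch, sprintf("part_%d.csv", w)))
    writeLines(sprintf("worker %d of %d: frames %s", w, plan@n_workers,
                       paste(plan@assignments[[w]], collapse = ",")),
               file.path(scratch, sprintf("config_%d.txt", w)))
    list(count = nLocalizations(tab),
         time_s = proc.time()[["elapsed"]] - t0, table = tab)
}

#' Run interleaved parallel localization
#'
#' Executes one localization worker per plan entry (isolated forked
#' processes via the local process pool, or serially), each processing its
#' strided frame subset, then merges the per-worker tables back into the
#' original frame order.  For the deterministic engines the merged table
#' is bit-identical to a single-worker run.
#'
#' @param handle a \linkS4class{MovieHandle}.
#' @param plan a \linkS4class{WorkerPlan}.
#' @param engine "nwls", "mle" or "phasor".
#' @param detection a \linkS4class{DetectionParams}.
#' @param calibration optional \linkS4class{AstigCalibration} (3D).
#' @param output_dir directory for merged outputs and worker scratch
#'   (default: a job-numbered directory next to the movie).
#' @param backend "fork" (process pool) or "serial".
#' @return A \linkS4class{RunReport}.
#' @export
runParallel <- function(handle, plan, engine = "nwls",
                        detection = detectionParams(), calibration = NULL,
                        output_dir = NULL, backend = c("fork", "serial")) {
    backend <- match.arg(backend)
    if (is.null(output_dir))
        output_dir <- file.path(dirname(handle@path), .job_id())
    scratch <- file.path(output_dir, "workers")
    dir.create(scratch, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(output_dir, "run.log")
    .log_line(log_path, sprintf(
        "parallel run: %s, %d frames, %d worker(s), engine=%s, %s",
        handle@path, plan@n_frames, plan@n_workers, engine,
        if (is.null(calibration)) "2D" else "3D"))
    workers <- seq_len(plan@n_workers)
    run_one <- function(w)
        tryCatch(.run_worker(w, handle, plan, engine, detection,
                             calibration, scratch),
                 error = function(e) list(error = conditionMessage(e),
                                          worker = w))
    results <- if (backend == "fork" && plan@n_workers > 1L &&
                   .Platform$OS.type == "unix")
        parallel::mclapply(workers, run_one,
                           mc.cores = min(plan@n_workers,
                                          max(parallel::detectCores(), 1L)))
    else lapply(workers, run_one)
    failed <- which(vapply(results, function(r) !is.null(r$error),
                           logical(1)))
    if (length(failed)) {
        w <- failed[1]
        .stop2("runError", sprintf(
            "worker %d (frames %s...) failed: %s; partial results under %s",
            w, paste(utils::head(plan@assignments[[w]], 4), collapse = ","),
            results[[w]]$error, scratch))
    }
    merged <- mergeTables(lapply(results, `[[`, "table"))
    merged_path <- file.path(output_dir, "localizations_raw.csv")
    writeLocalizations(merged, merged_path)
    ## concatenate worker logs into the run log, in worker order
    for (w in workers) {
        lw <- file.path(scratch, sprintf("log_%d.txt", w))
        if (file.exists(lw))
            cat(readLines(lw), file = log_path, sep = "\n", append = TRUE)
    }
    .log_line(log_path, sprintf("merged %d localizations -> %s",
                                nLocalizations(merged), merged_path))
    new("RunReport",
        worker_counts = vapply(results, function(r) as.integer(r$count),
                               integer(1)),
        worker_times_s = vapply(results, function(r) as.numeric(r$time_s),
                                numeric(1)),
        merged_path = merged_path, log_path = log_path,
        output_dir = output_dir, table = merged)
}

#' Export per-worker job manifests
#'
#' Writes one YAML job description per worker (input path, start frame,
#' stride, engine, detection parameters, calibration path) so an external
#' scheduler can execute the workers; grouping into nodes x jobs-per-node
#' is recorded for schedulers that allocate per node.
#'
#' @param handle a \linkS4class{MovieHandle}.
#' @param plan a \linkS4class{WorkerPlan}.
#' @param dir output directory for \code{worker_<w>.yaml} files.
#' @param engine localization engine name.
#' @param calibration_path optional calibration file path (3D).
#' @param jobs_per_node workers per node (manifest grouping only).
#' @return character vector of manifest paths, invisibly.
#' @export
exportManifests <- function(handle, plan, dir, engine = "nwls",
                            calibration_path = NULL, jobs_per_node = 1L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(seq_len(plan@n_workers), function(w) {
        p <- file.path(dir, sprintf("worker_%d.yaml", w))
        yaml::write_yaml(list(
            input = handle@path, worker = w,
            node = ((w - 1L) %/% as.integer(jobs_per_node)) + 1L,
            start = w, stride = plan@n_workers, engine = engine,
            calibration = calibration_path,
            output = sprintf("part_%d.csv", w)), p)
        p
    }, character(1))
    invisible(paths)
}

#' Process multiple movies in batch mode
#'
#' Dispatches movies to \code{n_slots} independent slots; each movie is
#' processed end-to-end (localization, postprocessing, rendering) inside
#' one slot using \code{jobs_per_node} internal workers, writing into its
#' own job-numbered output directory.  One movie failing does not abort
#' the others; failures are reported in the summary.
#'
#' @param movie_paths character vector of movie paths.
#' @param n_slots number of concurrent slots.
#' @param jobs_per_node internal workers per movie.
#' @param ... further arguments passed to \code{\link{runPipeline}}
#'   (engine, detection, postprocessing, rendering, calibration, ...).
#' @return list with one element per movie: a pipeline result list, or a
#'   \code{list(error = message)} entry for failures.
#' @export
runBatch <- function(movie_paths, n_slots = 1L, jobs_per_node = 1L, ...) {
    stopifnot(length(movie_paths) >= 1)
    run_one <- function(p)
        tryCatch(runPipeline(p, n_nodes = 1L,
                             jobs_per_node = jobs_per_node, ...),
                 error = function(e) list(error = conditionMessage(e),
                                          movie = p))
    results <- if (n_slots > 1L && .Platform$OS.type == "unix")
        parallel::mclapply(movie_paths, run_one,
                           mc.cores = min(as.integer(n_slots),
                                          length(movie_paths)))
    else lapply(movie_paths, run_one)
    names(results) <- movie_paths
    results
}
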