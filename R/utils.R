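## Internal helpers shared across modules.

## Timestamped human-readable log line, appended to `path` when non-NULL
## and echoed to the console when verbose.
.log_line <- function(path, msg, verbose = FALSE) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   " | ", msg)
    if (!is.null(path)) cat(line, "\n", sep = "", file = path, append = TRUE)
    if (verbose) message(line)
    invisible(line)
}

## Deterministic shortest decimal representation with <= 6 significant
## digits (integers exact) -- the CSV float dialect.
.fmt_num <- function(x) {
    out <- character(length(x))
    nax <- is.na(x)
    out[nax] <- "NA"
    out[!nax] <- vapply(signif(x[!nax], 6), function(v) {
        if (is.finite(v) && v == round(v) && abs(v) < 1e15)
            sprintf("%.0f", v)
        else as.character(v)
    }, character(1))
    out
}

## quantile() type 7 == linear interpolation between order statistics at
## rank p*(n-1); the package's single percentile convention.
.percentile <- function(x, p)
    unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))

## Unique job id: UTC timestamp + pid + in-session counter (mirrors
## scheduler job numbering for output subdirectories).  Does not touch the
## user's RNG stream, so seeded runs stay reproducible.
.pkg_env <- new.env(parent = emptyenv())
.pkg_env$job_counter <- 0L
.job_id <- function() {
    .pkg_env$job_counter <- .pkg_env$job_counter + 1L
    sprintf("%s_%d-%03d", format(Sys.time(), "%Y%m%dT%H%M%S", tz = "UTC"),
            Sys.getpid(), .pkg_env$job_counter)
}

.stop2 <- function(class, msg) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}
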