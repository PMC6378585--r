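#' @include AllClasses.R
NULL

## ThunderSTORM-dialect CSV header <-> internal column names.
.CSV_MAP <- c(`id` = "id", `frame` = "frame",
              `x [nm]` = "x_nm", `y [nm]` = "y_nm",
              `sigma [nm]` = "sigma_nm",
              `intensity [photon]` = "intensity_photons",
              `offset [photon]` = "offset_photons",
              `bkgstd [photon]` = "bkgstd_photons",
              `uncertainty_xy [nm]` = "uncertainty_xy_nm",
              `z [nm]` = "z_nm",
              `sigma1 [nm]` = "sigma1_nm", `sigma2 [nm]` = "sigma2_nm",
              `uncertainty_z [nm]` = "uncertainty_z_nm")

.CSV_HEADER_2D <- names(.CSV_MAP)[1:9]
.CSV_HEADER_3D <- c(names(.CSV_MAP)[1:9], "z [nm]", "sigma1 [nm]",
                    "sigma2 [nm]", "uncertainty_z [nm]")

#' Write a localization table as ThunderSTORM-compatible CSV
#'
#' Header fields are quoted, numbers are not; floats use the shortest
#' decimal representation with at most 6 significant digits.  Writing the
#' same table twice yields byte-identical files.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeLocalizations <- function(table, path) {
    stopifnot(is(table, "LocalizationTable"))
    validObject(table)
    header <- if (table@dim == 3L) .CSV_HEADER_3D else .CSV_HEADER_2D
    cols <- unname(.CSV_MAP[header])
    rec <- table@records
    lines <- paste0('"', paste(header, collapse = '","'), '"')
    if (nrow(rec)) {
        fields <- lapply(cols, function(cn) {
            v <- rec[[cn]]
            if (cn %in% c("id", "frame")) as.character(as.integer(v))
            else .fmt_num(v)
        })
        lines <- c(lines, do.call(paste, c(fields, sep = ",")))
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    invisible(path)
}

#' Read a ThunderSTORM-compatible localization CSV
#'
#' Dimensionality is inferred from the presence of a \code{"z [nm]"}
#' column.  Unknown columns raise a schema error; non-numeric cells raise
#' a parse error naming the row.
#'
#' @param path CSV path.
#' @return A \linkS4class{LocalizationTable}.
#' @export
readLocalizations <- function(path) {
    if (!file.exists(path)) .stop2("ioError", paste0("no such file: ", path))
    lines <- readLines(path)
    if (!length(lines)) .stop2("schemaError", "empty file, no header")
    header <- scan(text = lines[1], what = character(), sep = ",",
                   quiet = TRUE)
    unknown <- setdiff(header, names(.CSV_MAP))
    if (length(unknown))
        .stop2("schemaError", paste0("unknown column(s): ",
                                     paste(unknown, collapse = ", ")))
    if (!all(c("id", "frame", "x [nm]", "y [nm]") %in% header))
        .stop2("schemaError", "header lacks required columns")
    cols <- unname(.CSV_MAP[header])
    dim <- if ("z [nm]" %in% header) 3L else 2L
    body <- lines[-1]
    body <- body[nzchar(body)]
    rec <- stats::setNames(
        as.data.frame(matrix(numeric(0), 0, length(cols))), cols)
    if (length(body)) {
        cells <- strsplit(body, ",", fixed = TRUE)
        ncell <- lengths(cells)
        if (any(ncell != length(cols)))
            .stop2("parseError",
                   sprintf("row %d has %d fields, expected %d",
                           which(ncell != length(cols))[1],
                           ncell[ncell != length(cols)][1], length(cols)))
        m <- matrix(unlist(cells), ncol = length(cols), byrow = TRUE)
        num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
        bad <- which(is.na(num) & m != "NA", arr.ind = TRUE)
        if (nrow(bad))
            .stop2("parseError",
                   sprintf("non-numeric cell '%s' at row %d, column '%s'",
                           m[bad[1, 1], bad[1, 2]], bad[1, 1],
                           header[bad[1, 2]]))
        rec <- stats::setNames(as.data.frame(num), cols)
    }
    localizationTable(rec, dim = dim)
}
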