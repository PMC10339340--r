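## Localization-table IO in three dialects plus the pipeline's CSV sidecar
## files (chromatic-aberration parameters, ratio tables).
##
## Dialects (all defined by this package's own writers):
##   csv    — RFC-4180 CSV, header frame,x,y,intensity; x, y in nm; extra
##            columns are preserved on disk but ignored on read.
##   hdf5   — group /locs with datasets frame, x, y, intensity; x and y in
##            PIXELS, converted to nm on read using the pixel_size_nm
##            attribute (attributes: pixel_size_nm, n_frames, channel).
##   matlab — MAT v5 container with double column vectors frame, x, y (nm),
##            intensity and scalars pixel_size_nm, n_frames plus a channel
##            string; bridged through Python's scipy.io.
##
## All pipeline CSV outputs may carry leading '# key: value' comment lines;
## every reader here skips them.

.LOC_COLUMNS <- c("frame", "x", "y", "intensity")

#' Read a localization table
#'
#' @param path file to read.
#' @param dialect one of \code{"csv"}, \code{"hdf5"}, \code{"matlab"}.
#' @param channel channel label override (defaults to the label stored in
#'   the file, or \code{""} for the csv dialect).
#' @param pixelSize pixel size in nm; required metadata for the csv
#'   dialect (default 100), read from the file for hdf5/matlab.
#' @param nFrames number of frames; defaults to the stored value
#'   (hdf5/matlab) or \code{max(frame) + 1} (csv).
#' @param caModel optional \linkS4class{CAModel} (or path to a CA params
#'   CSV) applied to the coordinates immediately after loading.
#' @return a \linkS4class{LocalizationTable} with coordinates in nm.
#' @export
readLocalizations <- function(path, dialect = c("csv", "hdf5", "matlab"),
                              channel = NULL, pixelSize = NULL,
                              nFrames = NULL, caModel = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    tab <- switch(dialect,
                  csv = readLocsCsv(path, channel, pixelSize, nFrames),
                  hdf5 = readLocsH5(path, channel, pixelSize, nFrames),
                  matlab = readLocsMat(path, channel, pixelSize, nFrames))
    if (!is.null(caModel)) {
        if (is.character(caModel))
            caModel <- readCAParams(caModel)
        tab <- applyChromaticAberration(tab, caModel)
    }
    tab
}

#' Write a localization table
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param path output file.
#' @param dialect one of \code{"csv"}, \code{"hdf5"}, \code{"matlab"}.
#' @return \code{path}, invisibly.
#' @export
writeLocalizations <- function(table, path,
                               dialect = c("csv", "hdf5", "matlab")) {
    stopifnot(is(table, "LocalizationTable"))
    dialect <- match.arg(dialect)
    switch(dialect,
           csv = writeLocsCsv(table, path),
           hdf5 = writeLocsH5(table, path),
           matlab = writeLocsMat(table, path))
    invisible(path)
}

## ---- csv dialect ----

readLocsCsv <- function(path, channel, pixelSize, nFrames) {
    d <- freadNoComments(path)
    requireColumns(d, .LOC_COLUMNS, path)
    LocalizationTable(d$frame, d$x, d$y, d$intensity,
                      channel = if (is.null(channel)) "" else channel,
                      pixelSize = if (is.null(pixelSize)) 100 else pixelSize,
                      nFrames = nFrames)
}

writeLocsCsv <- function(table, path) {
    d <- locData(table)
    writeLines(c("frame,x,y,intensity",
                 sprintf("%d,%.17g,%.17g,%.17g",
                         d$frame, d$x, d$y, d$intensity)), path)
}

## ---- hdf5 dialect (coordinates stored in pixels) ----

readLocsH5 <- function(path, channel, pixelSize, nFrames) {
    contents <- tryCatch(rhdf5::h5ls(path),
                         error = function(e)
                             stop("unreadable HDF5 container: ", path,
                                  " (", conditionMessage(e), ")"))
    have <- contents$name[contents$group == "/locs"]
    missing <- setdiff(.LOC_COLUMNS, have)
    if (length(missing))
        stop("HDF5 file ", path, " is missing column(s): ",
             paste(missing, collapse = ", "))
    at <- rhdf5::h5readAttributes(path, "locs")
    px <- if (!is.null(pixelSize)) pixelSize
          else as.numeric(at$pixel_size_nm)
    nf <- if (!is.null(nFrames)) nFrames else as.integer(at$n_frames)
    ch <- if (!is.null(channel)) channel else as.character(at$channel)
    LocalizationTable(as.integer(rhdf5::h5read(path, "locs/frame")),
                      as.numeric(rhdf5::h5read(path, "locs/x")) * px,
                      as.numeric(rhdf5::h5read(path, "locs/y")) * px,
                      as.numeric(rhdf5::h5read(path, "locs/intensity")),
                      channel = ch, pixelSize = px, nFrames = nf)
}

writeLocsH5 <- function(table, path) {
    if (file.exists(path)) unlink(path)
    d <- locData(table)
    px <- pixelSize(table)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "locs")
    rhdf5::h5write(as.integer(d$frame), path, "locs/frame")
    rhdf5::h5write(d$x / px, path, "locs/x")
    rhdf5::h5write(d$y / px, path, "locs/y")
    rhdf5::h5write(d$intensity, path, "locs/intensity")
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, "locs")
    rhdf5::h5writeAttribute(px, gid, "pixel_size_nm")
    rhdf5::h5writeAttribute(nFrames(table), gid, "n_frames")
    rhdf5::h5writeAttribute(channelLabel(table), gid, "channel")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
}

## ---- matlab dialect (MAT v5 via the bundled Python bridge) ----

matBridge <- function() {
    script <- system.file("python", "mat_bridge.py", package = "dcColoc")
    if (script == "")
        stop("mat_bridge.py not found in the installed package")
    script
}

runBridge <- function(args) {
    out <- suppressWarnings(
        system2("python", args, stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
        stop("MATLAB dialect bridge failed: ",
             paste(out, collapse = "; "))
    invisible(out)
}

writeLocsMat <- function(table, path) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    writeLocsCsv(table, tmp)
    runBridge(c(shQuote(matBridge()), "write", shQuote(path), shQuote(tmp),
                shQuote(channelLabel(table)),
                sprintf("%.17g", pixelSize(table)),
                sprintf("%d", nFrames(table))))
}

readLocsMat <- function(path, channel, pixelSize, nFrames) {
    tmp <- tempfile(fileext = ".csv")
    meta <- tempfile(fileext = ".csv")
    on.exit(unlink(c(tmp, meta)))
    runBridge(c(shQuote(matBridge()), "read", shQuote(path), shQuote(tmp),
                shQuote(meta)))
    d <- freadNoComments(tmp)
    requireColumns(d, .LOC_COLUMNS, path)
    mt <- freadNoComments(meta)
    LocalizationTable(d$frame, d$x, d$y, d$intensity,
                      channel = if (!is.null(channel)) channel
                                else as.character(mt$channel[1L]),
                      pixelSize = if (!is.null(pixelSize)) pixelSize
                                  else as.numeric(mt$pixel_size_nm[1L]),
                      nFrames = if (!is.null(nFrames)) nFrames
                                else as.integer(mt$n_frames[1L]))
}

## ---- chromatic-aberration parameter files ----

.CA_COLUMNS <- c("reference_channel", "corrected_channel", "slope_x",
                 "intercept_x", "slope_y", "intercept_y")

#' Write / read chromatic-aberration parameters as CSV
#'
#' Columns: \code{reference_channel, corrected_channel, slope_x,
#' intercept_x, slope_y, intercept_y}. Round-trips to full float
#' precision.
#'
#' @param model a \linkS4class{CAModel}.
#' @param path CSV file.
#' @param comments optional character vector written as leading
#'   \code{# ...} lines.
#' @return \code{writeCAParams}: \code{path} invisibly;
#'   \code{readCAParams}: a \linkS4class{CAModel}.
#' @export
writeCAParams <- function(model, path, comments = NULL) {
    stopifnot(is(model, "CAModel"))
    validObject(model)
    lines <- c(commentLines(comments),
               paste(.CA_COLUMNS, collapse = ","),
               sprintf("%s,%s,%.17g,%.17g,%.17g,%.17g",
                       model@referenceChannel, model@correctedChannel,
                       model@slopeX, model@interceptX,
                       model@slopeY, model@interceptY))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeCAParams
#' @export
readCAParams <- function(path) {
    d <- freadNoComments(path)
    requireColumns(d, .CA_COLUMNS, path)
    if (nrow(d) != 1L)
        stop("CA parameter file must contain exactly one row: ", path)
    vals <- unlist(d[1L, c("slope_x", "intercept_x", "slope_y",
                           "intercept_y")])
    if (!all(is.finite(as.numeric(vals))))
        stop("CA parameter file has non-finite values: ", path)
    CAModel(slopeX = d$slope_x, interceptX = d$intercept_x,
            slopeY = d$slope_y, interceptY = d$intercept_y,
            referenceChannel = as.character(d$reference_channel),
            correctedChannel = as.character(d$corrected_channel))
}

## ---- ratio tables ----

#' Write / read a per-recording colocalization ratio table as CSV
#'
#' Columns: \code{recording_id, n_marker, n_coloc, ratio} and optionally
#' \code{known_state}. On read, the invariants 0 <= n_coloc <= n_marker
#' and ratio = n_coloc / n_marker (for n_marker > 0) are enforced.
#'
#' @param table \code{data.frame} as produced by \code{\link{ratioTable}}.
#' @param path CSV file.
#' @param comments optional character vector written as leading
#'   \code{# ...} lines.
#' @return \code{writeRatioTable}: \code{path} invisibly;
#'   \code{readRatioTable}: the validated \code{data.frame}.
#' @export
writeRatioTable <- function(table, path, comments = NULL) {
    need <- c("recording_id", "n_marker", "n_coloc", "ratio")
    requireColumns(table, need, "ratio table")
    hasState <- "known_state" %in% names(table)
    header <- paste(c(need, if (hasState) "known_state"), collapse = ",")
    rows <- sprintf("%s,%d,%d,%.17g", table$recording_id,
                    as.integer(table$n_marker), as.integer(table$n_coloc),
                    table$ratio)
    if (hasState)
        rows <- sprintf("%s,%d", rows, as.integer(table$known_state))
    writeLines(c(commentLines(comments), header, rows), path)
    invisible(path)
}

#' @rdname writeRatioTable
#' @export
readRatioTable <- function(path) {
    d <- freadNoComments(path)
    requireColumns(d, c("recording_id", "n_marker", "n_coloc", "ratio"),
                   path)
    d <- as.data.frame(d)
    if (any(d$n_coloc < 0L) || any(d$n_coloc > d$n_marker))
        stop("invalid ratio table ", path,
             ": need 0 <= n_coloc <= n_marker in every row")
    pos <- d$n_marker > 0L
    if (any(abs(d$ratio[pos] - d$n_coloc[pos] / d$n_marker[pos]) > 1e-9))
        stop("invalid ratio table ", path,
             ": ratio must equal n_coloc / n_marker")
    d
}

## ---- shared helpers ----

freadNoComments <- function(path) {
    first <- readLines(path, n = 200L)
    skip <- 0L
    while (skip < length(first) && startsWith(first[skip + 1L], "#"))
        skip <- skip + 1L
    as.data.frame(data.table::fread(path, skip = skip, header = TRUE,
                                    sep = ","))
}

requireColumns <- function(d, cols, what) {
    missing <- setdiff(cols, names(d))
    if (length(missing))
        stop("missing column(s) in ", what, ": ",
             paste(missing, collapse = ", "))
    invisible(TRUE)
}

commentLines <- function(comments) {
    if (is.null(comments)) character() else paste0("# ", comments)
}
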