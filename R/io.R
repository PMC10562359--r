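# File I/O: ESRI ASCII grids for rasters, strict CSV for tables, JSON for
# metadata. All rasters are validated against an expected grid at load;
# silent resampling is never performed.

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text raster exchange format (\code{ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value} header plus one row of values per line). Integer
#' layers round-trip bit-exactly; continuous layers round-trip within the
#' precision of the 15-significant-digit representation written.
#'
#' @param m numeric matrix (rows = grid rows, top row first).
#' @param path file path (.asc).
#' @param grid the [GridGeometry-class] of the layer.
#' @param nodata value written for NA cells.
#' @export
writeAsciiGrid <- function(m, path, grid, nodata = -9999) {
  if (!identical(dim(m), c(grid@nrow, grid@ncol)))
    stop(sprintf("layer shape (%s) does not match grid (%d x %d)",
                 paste(dim(m), collapse = " x "), grid@nrow, grid@ncol),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  yll <- grid@origin[2] - grid@nrow * grid@cellsize
  writeLines(c(sprintf("ncols %d", grid@ncol),
               sprintf("nrows %d", grid@nrow),
               sprintf("xllcorner %.6f", grid@origin[1]),
               sprintf("yllcorner %.6f", yll),
               sprintf("cellsize %.6f", grid@cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  writeLines(apply(mm, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @param expectedGrid optional [GridGeometry-class]; a geometry mismatch is
#'   an error naming both geometries.
#' @return \code{readAsciiGrid}: list with \code{values} (matrix) and
#'   \code{grid}.
#' @export
readAsciiGrid <- function(path, expectedGrid = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]),
                                 numeric(1)),
                          tolower(vapply(kv, `[`, character(1), 1)))
  grid <- gridGeom(vals[["nrows"]], vals[["ncols"]], vals[["cellsize"]],
                   origin = c(vals[["xllcorner"]],
                              vals[["yllcorner"]] +
                                vals[["nrows"]] * vals[["cellsize"]]))
  if (!is.null(expectedGrid)) .assertSameGrid(grid, expectedGrid,
                                              sprintf("'%s' and expected grid",
                                                      basename(path)))
  body <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  m[m == vals[["nodata_value"]]] <- NA
  list(values = m, grid = grid)
}

#' Strict CSV write / read
#'
#' Standard-dialect CSV (comma separator, period decimal mark). Reading
#' rejects files whose numeric-looking columns use locale comma decimals.
#'
#' @param d data.frame.
#' @param path file path.
#' @export
writeTableCsv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeTableCsv
#' @return \code{readTableCsv}: the data.frame.
#' @export
readTableCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  # a column like "1,5" everywhere indicates a comma-decimal dialect
  for (nm in names(d)) {
    v <- d[[nm]]
    if (is.character(v) && length(v) &&
        all(grepl("^-?[0-9]+,[0-9]+$", v[nzchar(v)])))
      stop(sprintf(paste("column '%s' in '%s' appears to use comma decimal",
                         "marks; only period-decimal CSV is supported"),
                   nm, basename(path)), call. = FALSE)
  }
  d
}

#' Write run metadata as JSON
#'
#' @param meta named list.
#' @param path file path.
#' @export
writeMetadataJson <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
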