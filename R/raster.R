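# Minimal single-band planar raster container ("pm_raster") plus ESRI
# ASCII-grid text I/O. Values are stored in a matrix with rows = northing
# (row 1 = top / max y), columns = easting, matching the .asc layout.

#' Create a planar raster
#'
#' @param values Numeric matrix, row 1 = northernmost row.
#' @param xmin,ymin Lower-left corner of the grid (m).
#' @param res Cell size (m).
#' @param nodata No-data value used on disk (default -9999).
#' @return Object of class `pm_raster`.
#' @export
make_raster <- function(values, xmin, ymin, res, nodata = -9999) {
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 res = res, nodata = nodata),
            class = "pm_raster")
}

#' @export
print.pm_raster <- function(x, ...) {
  cat("pm_raster:", nrow(x$values), "rows x", ncol(x$values), "cols,",
      "res", x$res, "m, origin (", x$xmin, ",", x$ymin, ")\n")
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat("values: min", format(min(v), digits = 4),
        " mean", format(mean(v), digits = 4),
        " max", format(max(v), digits = 4), "\n")
  invisible(x)
}

# Cell-centre coordinates aligned with values (vectorised, column-major).
raster_cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  xs <- r$xmin + (seq_len(nc) - 0.5) * r$res
  ys <- r$ymin + (nr - seq_len(nr) + 0.5) * r$res # row 1 = top
  list(x = rep(xs, each = nr), y = rep(ys, times = nc),
       row = rep(seq_len(nr), times = nc), col = rep(seq_len(nc), each = nr))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format readable by standard GIS software.
#'
#' @param r A `pm_raster`.
#' @param path Output file path.
#' @param digits Significant digits written (default 6).
#' @export
write_raster_asc <- function(r, path, digits = 6) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xmin, scientific = FALSE)),
    paste("yllcorner", format(r$ymin, scientific = FALSE)),
    paste("cellsize", format(r$res, scientific = FALSE)),
    paste("NODATA_value", r$nodata)
  )
  body <- apply(signif(v, digits), 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path `.asc` file path.
#' @return A `pm_raster` (no-data cells become `NA`).
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    if (length(ln) != 1L) stop("malformed .asc header in ", path)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  xmin <- val("xllcorner"); ymin <- val("yllcorner")
  res <- val("cellsize"); nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  if (length(body) != nr) stop("row count mismatch in ", path)
  m <- do.call(rbind, lapply(body, function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  if (ncol(m) != nc) stop("column count mismatch in ", path)
  m[m == nodata] <- NA
  make_raster(m, xmin, ymin, res, nodata)
}
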