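# Minimal GeoJSON reader/writer for the package's planar rectangles and
# road segments, built on jsonlite. Coordinates are written with fixed
# precision so identical inputs give byte-identical files.

#' Write rectangles or segments as GeoJSON
#'
#' Rows with `xmin`/`ymin`/`xmax`/`ymax` become Polygon features; rows
#' with `x1`/`y1`/`x2`/`y2` become LineString features. All other columns
#' are written as feature properties.
#'
#' @param df data.frame of rectangles or segments.
#' @param path Output path.
#' @param digits Coordinate decimal places (default 3).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(df, path, digits = 3) {
  is_rect <- all(c("xmin", "ymin", "xmax", "ymax") %in% colnames(df))
  geom_cols <- if (is_rect) c("xmin", "ymin", "xmax", "ymax")
  else c("x1", "y1", "x2", "y2")
  if (!all(geom_cols %in% colnames(df)))
    stop("no recognisable geometry columns in data frame")
  props <- setdiff(colnames(df), geom_cols)
  rnd <- function(v) round(v, digits)
  feats <- lapply(seq_len(nrow(df)), function(i) {
    geom <- if (is_rect) {
      ring <- close_ring(rect_poly(df$xmin[i], df$ymin[i],
                                   df$xmax[i], df$ymax[i]))
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(k)
             c(rnd(ring[k, 1]), rnd(ring[k, 2])))))
    } else {
      list(type = "LineString",
           coordinates = list(c(rnd(df$x1[i]), rnd(df$y1[i])),
                              c(rnd(df$x2[i]), rnd(df$y2[i]))))
    }
    pr <- lapply(props, function(p) {
      v <- df[[p]][i]
      if (is.numeric(v)) round(v, 6) else v
    })
    names(pr) <- props
    list(type = "Feature", properties = pr, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a GeoJSON file written by [write_geojson()]
#'
#' Polygons are returned as their bounding rectangles (the package's
#' geometries are axis-aligned rectangles, so this is lossless);
#' LineStrings as end-point segments. Properties become columns.
#'
#' @param path GeoJSON file path.
#' @return data.frame with geometry columns and properties.
#' @export
read_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("not a FeatureCollection: ", path)
  rows <- lapply(seq_along(g$features), function(i) {
    f <- g$features[[i]]
    geom <- f$geometry
    if (is.null(geom$type) || is.null(geom$coordinates))
      stop("malformed geometry in ", path, " at feature ", i)
    coords <- geom$coordinates
    gcols <- if (geom$type == "Polygon") {
      ring <- coords[[1]]
      if (length(ring) < 4) stop("degenerate ring in ", path,
                                 " at feature ", i)
      xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
      ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
      if (any(!is.finite(xs)) || any(!is.finite(ys)))
        stop("non-numeric coordinates in ", path, " at feature ", i)
      list(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
    } else if (geom$type == "LineString") {
      p1 <- coords[[1]]; p2 <- coords[[length(coords)]]
      list(x1 = as.numeric(p1[[1]]), y1 = as.numeric(p1[[2]]),
           x2 = as.numeric(p2[[1]]), y2 = as.numeric(p2[[2]]))
    } else stop("unsupported geometry type '", geom$type, "' in ", path)
    pr <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    as.data.frame(c(pr, gcols), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a monitoring panel CSV with schema validation
#'
#' @param path CSV path.
#' @return data.frame; errors name the file and the missing field.
#' @export
read_panel <- function(path) {
  need <- c("site_id", "month", "x", "y", "PM25",
            "PRS", "PRS_Sea", "WIN", "TEM", "RHU", "PRE_1h")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  d
}
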