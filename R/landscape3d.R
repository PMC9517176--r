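# Building heights, height categories and the six 3D landscape pattern
# indices computed per sample area (function zone).

#' Building height category table
#'
#' The eight built-form categories used throughout the package, defined by
#' the height intervals attained under standard floor heights (2.8 m for
#' civil buildings, 5.0 m for industrial plants). The printed intervals do
#' not partition the positive axis: heights falling in an inter-bin gap are
#' assigned to the category with the nearest interval endpoint (ties go to
#' the lower category), so every positive height maps to exactly one
#' category.
#'
#' @return A data.frame with columns `category`, `lower` and `upper` (m).
#' @seealso [classify_height()]
#' @export
#' @examples
#' height_categories()
height_categories <- function() {
  data.frame(
    category = c("bungalow", "low-rise", "multistory", "high-rise",
                 "high-rise-1", "high-rise-2", "high-rise-3",
                 "super-high-rise"),
    lower = c(2.8, 5.6, 11.2, 19.6, 30.8, 53.2, 73.2, 100.0),
    upper = c(5.0, 10.0, 15.0, 28.0, 50.4, 70.0, 98.0, Inf),
    stringsAsFactors = FALSE
  )
}

#' Estimate building height from floor count
#'
#' Industrial (plant) buildings are assigned 5.0 m per floor, all other use
#' classes the standard civil floor height of 2.8 m.
#'
#' @param floors Integer vector of floor counts (>= 1).
#' @param use_class Character vector of building use classes; `"industrial"`
#'   selects the plant floor height.
#' @return Numeric vector of heights in metres.
#' @export
#' @examples
#' estimate_height(10, "residential") # 28 m
#' estimate_height(2, "industrial")   # 10 m
estimate_height <- function(floors, use_class) {
  if (any(is.na(floors)) || any(floors < 1))
    stop("`floors` must be >= 1")
  per <- ifelse(use_class == "industrial", 5.0, 2.8)
  floors * per
}

#' Classify a building height into one of eight categories
#'
#' @param height Numeric vector of building heights in metres (> 0).
#' @return Character vector of category names (see [height_categories()]).
#' @export
#' @examples
#' classify_height(c(4, 17, 120))
classify_height <- function(height) {
  if (any(is.na(height)) || any(height <= 0))
    stop("`height` must be positive")
  cats <- height_categories()
  k <- nrow(cats)
  out <- character(length(height))
  for (i in seq_along(height)) {
    h <- height[i]
    hit <- which(h >= cats$lower & h <= cats$upper)
    if (length(hit) >= 1L) {
      out[i] <- cats$category[hit[1L]]
      next
    }
    # gap (or below the first bin): nearest interval endpoint, ties lower
    ends <- c(rbind(cats$lower, pmin(cats$upper, cats$lower + 1e6)))
    idx <- rep(seq_len(k), each = 2L)
    d <- abs(h - ends)
    best <- which(d == min(d))
    out[i] <- cats$category[min(idx[best])]
  }
  out
}

check_sample <- function(heights, what = "sample area") {
  if (length(heights) < 1L)
    stop("empty ", what, ": at least one building required")
  if (any(heights <= 0)) stop("building heights must be positive")
  invisible(TRUE)
}

#' Landscape height density
#'
#' Mean building height of the sample area, in metres.
#'
#' @param heights Numeric vector of member building heights (m).
#' @return Mean height (m).
#' @export
height_density <- function(heights) {
  check_sample(heights)
  mean(heights)
}

#' Landscape volume density
#'
#' Built-volume fraction of the bounding prism: `sum(V_i) / (Hmax * S)`,
#' where `V_i` is building volume, `Hmax` the tallest building and `S` the
#' sample-area extent. Equals 1 for a single prism filling the area.
#'
#' @param volumes Numeric vector of building volumes (m^3).
#' @param heights Numeric vector of building heights (m), same length.
#' @param area Sample-area extent S (m^2).
#' @return Dimensionless fraction.
#' @export
volume_density <- function(volumes, heights, area) {
  check_sample(heights)
  if (length(volumes) != length(heights))
    stop("`volumes` and `heights` lengths differ")
  if (area <= 0) stop("`area` must be positive")
  sum(volumes) / (max(heights) * area)
}

#' Landscape spatial dispersion
#'
#' Coefficient of variation of building heights: population standard
#' deviation (1/n) divided by the mean. Zero iff all member heights are
#' equal.
#'
#' @inheritParams height_density
#' @return Dimensionless dispersion.
#' @export
spatial_dispersion <- function(heights) {
  check_sample(heights)
  m <- mean(heights)
  sqrt(mean((heights - m)^2)) / m
}

#' Landscape fluctuation
#'
#' Height relief of the sample area: `Hmax - Hmin` in metres. Also called
#' landscape undulation.
#'
#' @inheritParams height_density
#' @return Height range (m).
#' @export
fluctuation <- function(heights) {
  check_sample(heights)
  max(heights) - min(heights)
}

#' Building diversity
#'
#' Shannon entropy (nats) of the footprint-area shares of the eight height
#' categories present in the sample area. Categories with zero share
#' contribute nothing; a single-category sample has diversity 0.
#'
#' @param heights Numeric vector of member building heights (m).
#' @param fp_areas Numeric vector of footprint areas (m^2), same length.
#' @return Entropy in nats, at most `log(8)`.
#' @export
building_diversity <- function(heights, fp_areas) {
  check_sample(heights)
  if (length(fp_areas) != length(heights))
    stop("`fp_areas` and `heights` lengths differ")
  p <- category_shares(heights, fp_areas)
  p <- p[p > 0]
  -sum(p * log(p))
}

category_shares <- function(heights, fp_areas) {
  cat <- classify_height(heights)
  tot <- tapply(fp_areas, cat, sum)
  as.numeric(tot) / sum(fp_areas)
}

#' Building uniformity
#'
#' Building diversity expressed as a percentage of its maximum
#' `Smax = log(m)`, with `m` the number of height categories present in the
#' sample (`smax_global = TRUE` uses all eight categories instead). With a
#' single category present the uniformity is defined as 0.
#'
#' @inheritParams building_diversity
#' @param smax_global If `TRUE`, normalise by `log(8)` rather than by the
#'   number of categories present.
#' @return Percentage in \[0, 100\].
#' @export
building_uniformity <- function(heights, fp_areas, smax_global = FALSE) {
  check_sample(heights)
  p <- category_shares(heights, fp_areas)
  m <- if (smax_global) 8L else length(p)
  if (m <= 1L) return(0)
  s <- building_diversity(heights, fp_areas)
  100 * s / log(m)
}

#' All six 3D landscape indices of one sample area
#'
#' @param buildings A data.frame with columns `height` (m), `fp_area`
#'   (m^2) and `volume` (m^3); `volume` defaults to `fp_area * height`
#'   when absent.
#' @param area Sample-area extent S (m^2).
#' @param smax_global Passed to [building_uniformity()].
#' @return Named numeric vector with elements `H_bar`, `E_vol`, `L`,
#'   `LHR`, `S_div`, `E_uni`.
#' @export
#' @examples
#' b <- data.frame(height = c(5.6, 28, 28, 84),
#'                 fp_area = c(100, 200, 100, 50))
#' index_vector(b, area = 1e4)
index_vector <- function(buildings, area, smax_global = FALSE) {
  if (is.null(buildings$height) || nrow(buildings) < 1L)
    stop("sample area has no buildings")
  h <- buildings$height
  fp <- buildings$fp_area
  v <- buildings$volume
  if (is.null(v)) v <- fp * h
  c(H_bar = height_density(h),
    E_vol = volume_density(v, h, area),
    L = spatial_dispersion(h),
    LHR = fluctuation(h),
    S_div = building_diversity(h, fp),
    E_uni = building_uniformity(h, fp, smax_global = smax_global))
}

#' 3D landscape indices for every function zone
#'
#' Assigns buildings to zones by footprint-centroid containment and
#' computes the six indices zone by zone.
#'
#' @param zones Zone table as returned by [identify_zones()].
#' @param buildings Building table as returned by [generate_buildings()].
#' @param smax_global Passed to [building_uniformity()].
#' @return data.frame with `zone_id`, `zone_type` and columns `H_bar`,
#'   `E_vol`, `L`, `LHR`, `S_div`, `E_uni`; zones without buildings are
#'   dropped with a warning.
#' @export
landscape_indices <- function(zones, buildings, smax_global = FALSE) {
  stopifnot(nrow(zones) >= 1L)
  cx <- (buildings$xmin + buildings$xmax) / 2
  cy <- (buildings$ymin + buildings$ymax) / 2
  out <- vector("list", nrow(zones))
  for (i in seq_len(nrow(zones))) {
    z <- zones[i, ]
    sel <- cx >= z$xmin & cx <= z$xmax & cy >= z$ymin & cy <= z$ymax
    if (!any(sel)) next
    b <- buildings[sel, , drop = FALSE]
    iv <- index_vector(
      data.frame(height = b$height, fp_area = b$fp_area, volume = b$volume),
      area = (z$xmax - z$xmin) * (z$ymax - z$ymin),
      smax_global = smax_global
    )
    out[[i]] <- data.frame(zone_id = z$zone_id, zone_type = z$zone_type,
                           t(iv), stringsAsFactors = FALSE)
  }
  empty <- vapply(out, is.null, logical(1))
  if (any(empty))
    warning(sum(empty), " zone(s) without buildings dropped")
  do.call(rbind, out[!empty])
}
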