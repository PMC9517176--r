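# Identification of urban land-function zones from parcel composition.
# A candidate polygon becomes a residential/commercial/educational zone when
# that class occupies strictly more than 50% of its area, an industrial zone
# when industrial land occupies strictly more than 40%; otherwise it is left
# unclassified ("mixed").

zone_thresholds <- c(residential = 0.5, commercial = 0.5,
                     educational = 0.5, industrial = 0.4)

#' Classify a land-use composition into a function-zone type
#'
#' @param shares Named numeric vector of land-use class area shares in
#'   \[0, 1\] (need not sum to 1; the remainder is unclassified land).
#' @return One of `"residential"`, `"commercial"`, `"industrial"`,
#'   `"educational"`, or `NA_character_` when no dominance rule fires.
#'   When several rules fire the largest share wins; an exact tie gives
#'   `NA` (conservative).
#' @export
#' @examples
#' classify_zone(c(residential = 0.6, other = 0.4))  # residential
#' classify_zone(c(industrial = 0.45, other = 0.55)) # industrial
#' classify_zone(c(residential = 0.5))               # NA: strictly > 0.5
classify_zone <- function(shares) {
  if (any(is.na(shares)) || any(shares < 0))
    stop("shares must be non-negative")
  if (sum(shares) > 1 + 1e-9)
    stop("shares sum to more than 1")
  fired <- names(zone_thresholds)[
    vapply(names(zone_thresholds), function(cl) {
      s <- if (cl %in% names(shares)) shares[[cl]] else 0
      s > zone_thresholds[[cl]]
    }, logical(1))
  ]
  if (length(fired) == 0L) return(NA_character_)
  if (length(fired) == 1L) return(fired)
  s <- vapply(fired, function(cl) shares[[cl]], numeric(1))
  top <- fired[s == max(s)]
  if (length(top) > 1L) return(NA_character_) # tie
  top
}

# Area shares of each land-use class inside a candidate rectangle,
# computed from exact rectangle-rectangle intersections.
candidate_composition <- function(cand, parcels) {
  a <- rect_intersect_area(parcels$xmin, parcels$ymin,
                           parcels$xmax, parcels$ymax,
                           cand$xmin, cand$ymin, cand$xmax, cand$ymax)
  tot <- (cand$xmax - cand$xmin) * (cand$ymax - cand$ymin)
  if (tot <= 0) stop("degenerate candidate geometry (zero area)")
  sh <- tapply(a, parcels$class, sum) / tot
  sh <- sh[sh > 0]
  stats::setNames(as.numeric(sh), names(sh))
}

#' Identify function zones among candidate polygons
#'
#' Computes each candidate's land-use composition by intersecting it with
#' the parcel mosaic, applies the dominance rules of [classify_zone()],
#' and drops unclassified candidates.
#'
#' @param parcels Parcel table (rectangles with a `class` column), e.g.
#'   `generate_parcels(cfg)$parcels`.
#' @param candidates Candidate table with `cand_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax`.
#' @return data.frame of zones: `zone_id`, `zone_type`, rectangle bounds,
#'   `area_km2`, centroid `x`, `y`.
#' @seealso [zone_summary()]
#' @export
identify_zones <- function(parcels, candidates) {
  stopifnot(nrow(candidates) >= 1L)
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    if (!is.finite(cand$xmin) || cand$xmax <= cand$xmin ||
        cand$ymax <= cand$ymin)
      stop("invalid geometry for candidate ", cand$cand_id)
    type <- classify_zone(candidate_composition(cand, parcels))
    if (is.na(type)) next
    rows[[i]] <- data.frame(
      zone_id = cand$cand_id, zone_type = type,
      xmin = cand$xmin, ymin = cand$ymin,
      xmax = cand$xmax, ymax = cand$ymax,
      area_km2 = (cand$xmax - cand$xmin) * (cand$ymax - cand$ymin) / 1e6,
      x = (cand$xmin + cand$xmax) / 2, y = (cand$ymin + cand$ymax) / 2,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(zone_id = character(), zone_type = character(),
                      xmin = numeric(), ymin = numeric(), xmax = numeric(),
                      ymax = numeric(), area_km2 = numeric(),
                      x = numeric(), y = numeric())
  out
}

#' Per-type summary of identified zones
#'
#' @param zones Output of [identify_zones()].
#' @return data.frame with one row per zone type: count and min/max/mean
#'   area (km^2).
#' @export
zone_summary <- function(zones) {
  if (nrow(zones) == 0L)
    return(data.frame(zone_type = character(), n = integer(),
                      min_km2 = numeric(), max_km2 = numeric(),
                      mean_km2 = numeric()))
  sp <- split(zones$area_km2, zones$zone_type)
  data.frame(
    zone_type = names(sp),
    n = vapply(sp, length, integer(1)),
    min_km2 = vapply(sp, min, numeric(1)),
    max_km2 = vapply(sp, max, numeric(1)),
    mean_km2 = vapply(sp, mean, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
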