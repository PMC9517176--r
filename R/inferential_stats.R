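# Zonal aggregation and classical inference: one-way ANOVA with LSD post
# hoc comparisons across zone types, and Pearson correlation of indices
# with zonal PM2.5. Model fitting is delegated to stats::lm / stats::anova;
# LSD standard errors use the pooled within-group mean square.

#' Zonal mean of a raster
#'
#' Mean of the raster cells whose centres fall inside the zone rectangle.
#'
#' @param raster A `pm_raster` (see [make_raster()]).
#' @param zone One-row data.frame with `xmin`, `ymin`, `xmax`, `ymax` (and
#'   optionally `zone_id` used in error messages).
#' @return Mean cell value.
#' @export
zonal_mean_pm25 <- function(raster, zone) {
  cc <- raster_cell_centres(raster)
  sel <- cc$x >= zone$xmin & cc$x <= zone$xmax &
    cc$y >= zone$ymin & cc$y <= zone$ymax
  vals <- raster$values[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    id <- if (!is.null(zone$zone_id)) zone$zone_id else "<unnamed>"
    stop("no raster cells inside zone ", id)
  }
  mean(vals)
}

#' One-way analysis of variance
#'
#' Standard one-way decomposition (between/within sums of squares); with a
#' single factor the Type III and sequential decompositions coincide, so
#' the table is computed through `stats::lm`/`stats::anova`.
#'
#' @param groups A named list of numeric vectors, one per group (>= 2
#'   groups, each with >= 2 values).
#' @return An object of class `anova_table`: data.frame with rows
#'   between/within/total and columns `ss`, `df`, `ms`, `F`, `p`.
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least two values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  a <- stats::anova(stats::lm(y ~ g))
  out <- data.frame(
    source = c("between", "within", "total"),
    ss = c(a$`Sum Sq`, sum(a$`Sum Sq`)),
    df = c(a$Df, sum(a$Df)),
    ms = c(a$`Mean Sq`, NA),
    F = c(a$F[1], NA, NA),
    p = c(a$`Pr(>F)`[1], NA, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' LSD post hoc pairwise comparisons
#'
#' Fisher's least-significant-difference comparisons after a one-way
#' ANOVA: for each ordered pair of groups the mean difference, its pooled
#' standard error `sqrt(MSW * (1/nI + 1/nJ))`, and a two-sided p-value
#' from the t distribution on the within-group degrees of freedom. No
#' multiplicity adjustment is applied (that is what LSD means).
#'
#' @inheritParams one_way_anova
#' @return data.frame with columns `group_i`, `group_j`, `diff`, `se`,
#'   `t`, `p`; antisymmetric in the pair order.
#' @export
lsd_posthoc <- function(groups) {
  at <- one_way_anova(groups)
  msw <- at$ms[2]
  dfw <- at$df[2]
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  mns <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, numeric(1))
  pairs <- expand.grid(i = seq_along(groups), j = seq_along(groups))
  pairs <- pairs[pairs$i != pairs$j, ]
  d <- mns[pairs$i] - mns[pairs$j]
  se <- sqrt(msw * (1 / ns[pairs$i] + 1 / ns[pairs$j]))
  tv <- d / se
  data.frame(
    group_i = nm[pairs$i], group_j = nm[pairs$j],
    diff = unname(d), se = unname(se), t = unname(tv),
    p = unname(2 * stats::pt(-abs(tv), dfw)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors (length >= 3, both non-constant).
#' @return Named list with `r` and `p` (two-sided).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation table of 3D indices vs zonal PM2.5 per zone type
#'
#' @param indices Output of [landscape_indices()].
#' @param pm25 Numeric vector of zonal mean PM2.5 aligned with
#'   `indices` rows.
#' @return data.frame: one row per (zone type, index) with `r` and `p`;
#'   index/type combinations with a constant column are skipped.
#' @export
index_pm25_correlations <- function(indices, pm25) {
  idx_cols <- c("H_bar", "E_vol", "L", "LHR", "S_div", "E_uni")
  rows <- list()
  for (ty in unique(indices$zone_type)) {
    sel <- indices$zone_type == ty
    for (cl in idx_cols) {
      x <- indices[[cl]][sel]; y <- pm25[sel]
      if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) next
      pr <- pearson_r(x, y)
      rows[[length(rows) + 1L]] <-
        data.frame(zone_type = ty, index = cl, r = pr$r, p = pr$p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Study-area density of monitoring sites
#'
#' Convenience arithmetic: area served per monitoring site.
#'
#' @param area_km2 Study-area extent (km^2).
#' @param n_sites Number of monitoring sites.
#' @return km^2 per site.
#' @export
#' @examples
#' area_per_site(562.46, 16)
area_per_site <- function(area_km2, n_sites) {
  stopifnot(area_km2 > 0, n_sites >= 1)
  area_km2 / n_sites
}
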