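# Internal planar-geometry primitives. All coordinates are metres on a local
# Euclidean grid; no geodetic CRS handling anywhere in the package.

#' Polygon area by the shoelace formula
#'
#' @param xy two-column matrix of vertices (open or closed ring).
#' @return Non-negative area in squared coordinate units.
#' @keywords internal
#' @noRd
poly_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1L)) # previous vertex
  abs(sum(x[j] * y - x * y[j])) / 2
}

poly_centroid <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# Clip polygon to half-plane a*x + b*y <= c (Sutherland-Hodgman step).
clip_halfplane <- function(xy, a, b, c) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(xy[0, , drop = FALSE])
  d <- a * xy[, 1] + b * xy[, 2] - c
  if (all(d <= 0)) return(xy)
  if (all(d > 0)) return(xy[0, , drop = FALSE])
  out_x <- numeric(2L * n); out_y <- numeric(2L * n); k <- 0L
  jprev <- n
  for (i in seq_len(n)) {
    di <- d[i]; dj <- d[jprev]
    if (dj <= 0) {
      if (di <= 0) {           # in -> in
        k <- k + 1L; out_x[k] <- xy[i, 1]; out_y[k] <- xy[i, 2]
      } else {                 # in -> out: add intersection
        t <- dj / (dj - di)
        k <- k + 1L
        out_x[k] <- xy[jprev, 1] + t * (xy[i, 1] - xy[jprev, 1])
        out_y[k] <- xy[jprev, 2] + t * (xy[i, 2] - xy[jprev, 2])
      }
    } else {
      if (di <= 0) {           # out -> in: intersection then vertex
        t <- dj / (dj - di)
        k <- k + 1L
        out_x[k] <- xy[jprev, 1] + t * (xy[i, 1] - xy[jprev, 1])
        out_y[k] <- xy[jprev, 2] + t * (xy[i, 2] - xy[jprev, 2])
        k <- k + 1L; out_x[k] <- xy[i, 1]; out_y[k] <- xy[i, 2]
      }                        # out -> out: nothing
    }
    jprev <- i
  }
  cbind(out_x[seq_len(k)], out_y[seq_len(k)])
}

# Clip polygon to axis-aligned rectangle.
clip_rect <- function(xy, xmin, ymin, xmax, ymax) {
  xy <- clip_halfplane(xy, -1, 0, -xmin)
  xy <- clip_halfplane(xy, 1, 0, xmax)
  xy <- clip_halfplane(xy, 0, -1, -ymin)
  clip_halfplane(xy, 0, 1, ymax)
}

# Regular polygon approximating a circle; n even keeps both axis symmetries.
circle_poly <- function(cx, cy, r, n = 128L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Area of intersection of two axis-aligned rectangles (exact).
rect_intersect_area <- function(ax0, ay0, ax1, ay1, bx0, by0, bx1, by1) {
  w <- pmin(ax1, bx1) - pmax(ax0, bx0)
  h <- pmin(ay1, by1) - pmax(ay0, by0)
  ifelse(w > 0 & h > 0, w * h, 0)
}

# Length of the part of segment (x1,y1)-(x2,y2) inside circle (cx,cy,r).
seg_circle_len <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(0)
  fx <- x1 - cx; fy <- y1 - cy
  a <- L2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  if (disc <= 0) return(0)
  sq <- sqrt(disc)
  t0 <- max(0, (-b - sq) / (2 * a))
  t1 <- min(1, (-b + sq) / (2 * a))
  if (t1 <= t0) return(0)
  (t1 - t0) * sqrt(L2)
}

# Even-odd ray-casting point-in-polygon; vectorised over points.
points_in_poly <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  xs <- xy[, 1]; ys <- xy[, 2]
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

# Close a ring (repeat first vertex) for GeoJSON output.
close_ring <- function(xy) rbind(xy, xy[1, , drop = FALSE])
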