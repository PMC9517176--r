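# Geographically weighted regression: local weighted least squares with a
# Gaussian distance-decay kernel, AICc bandwidth selection by
# golden-section search, and Moran's I residual diagnostics with a
# permutation test on inverse-distance weights.

#' Select the two index predictors for GWR
#'
#' Picks the index most correlated (absolute Pearson) with zonal PM2.5,
#' then the strongest remaining index whose absolute correlation with the
#' first is below `rcut`. If no second index qualifies, the single index
#' is returned with a warning.
#'
#' @param indices data.frame of numeric index columns (one row per zone).
#' @param pm25 Zonal mean PM2.5 aligned with `indices` rows.
#' @param rcut Collinearity cutoff (default 0.6, strict).
#' @return Character vector of one or two index names.
#' @export
select_gwr_predictors <- function(indices, pm25, rcut = 0.6) {
  num <- vapply(indices, is.numeric, logical(1))
  X <- as.matrix(indices[, num, drop = FALSE])
  ok <- apply(X, 2, stats::sd) > 0
  X <- X[, ok, drop = FALSE]
  if (ncol(X) < 1L) stop("no usable (non-constant) index columns")
  r <- abs(drop(stats::cor(X, pm25)))
  first <- colnames(X)[which.max(r)]
  others <- setdiff(colnames(X)[order(-r)], first)
  for (v in others) {
    if (abs(stats::cor(X[, first], X[, v])) < rcut) return(c(first, v))
  }
  warning("no second index with |r| < ", rcut, " against ", first,
          "; returning a single predictor")
  first
}

gwr_kernel <- function(d, bandwidth, kernel = "gaussian") {
  switch(kernel,
         gaussian = exp(-(d / bandwidth)^2),
         stop("unknown kernel: ", kernel))
}

#' Fit a geographically weighted regression
#'
#' At every observation location a weighted least-squares regression is
#' solved with Gaussian kernel weights `w_ij = exp(-(d_ij / b)^2)`,
#' giving a local intercept and local slopes per location. Fit statistics
#' use the standard GWR hat-matrix trace (effective number of
#' parameters); standardized residuals are internally studentized. A
#' singular local design falls back to a small ridge with a warning.
#'
#' @param coords Two-column matrix/data.frame of locations (m).
#' @param y Response vector.
#' @param X Covariate matrix or data.frame (without intercept).
#' @param bandwidth Kernel bandwidth (m, > 0).
#' @param kernel Kernel name (only `"gaussian"`).
#' @param morans Compute Moran's I of the standardized residuals.
#' @param nperm,moran_seed Permutation settings passed to [morans_i()].
#' @return Object of class `gwr_fit`: local `coefficients` (one row per
#'   location), `fitted`, `residuals`, `std_residuals`, hat diagonal,
#'   `enp`, `r_squared`, `adj_r_squared`, `aicc`, `bandwidth`, `kernel`,
#'   and `morans` (list or `NULL`).
#' @export
fit_gwr <- function(coords, y, X, bandwidth, kernel = "gaussian",
                    morans = TRUE, nperm = 999, moran_seed = 1L) {
  coords <- as.matrix(coords)
  X <- as.matrix(X)
  n <- length(y)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  if (n < p + 2) stop("need n >= p + 2 observations")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  D <- as.matrix(stats::dist(coords))
  B <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(Xd)))
  hat <- numeric(n)
  ridge_used <- FALSE
  for (i in seq_len(n)) {
    w <- gwr_kernel(D[i, ], bandwidth, kernel)
    Xw <- Xd * w
    A <- crossprod(Xd, Xw)
    b <- crossprod(Xw, y)
    sol <- tryCatch(solve(A, cbind(b, Xd[i, ])), error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol))) {
      ridge_used <- TRUE
      A <- A + diag(1e-8 * mean(diag(A)), p)
      sol <- solve(A, cbind(b, Xd[i, ]))
    }
    B[i, ] <- sol[, 1]
    hat[i] <- sum(Xd[i, ] * sol[, 2]) * w[i]
  }
  if (ridge_used)
    warning("singular local design at one or more locations; ridge fallback")
  fitted <- rowSums(Xd * B)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  enp <- sum(hat)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - enp)
  aicc <- if (n - 2 - enp > 0)
    n * log(rss / n) + n * log(2 * pi) + n * (n + enp) / (n - 2 - enp)
  else Inf
  sigma2 <- rss / max(n - enp, 1e-8)
  std_res <- resid / sqrt(sigma2 * pmax(1 - hat, 1e-8))
  mor <- NULL
  if (morans && stats::sd(std_res) > 0)
    mor <- morans_i(std_res, coords, nperm = nperm, seed = moran_seed)
  structure(list(coords = coords, coefficients = B, fitted = fitted,
                 residuals = resid, std_residuals = std_res, hat = hat,
                 enp = enp, bandwidth = bandwidth, kernel = kernel,
                 r_squared = r2, adj_r_squared = adj_r2, aicc = aicc,
                 morans = mor, y = y),
            class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat("GWR fit:", length(x$y), "locations,", ncol(x$coefficients) - 1,
      "covariate(s), bandwidth", round(x$bandwidth), "m (", x$kernel, ")\n")
  cat("R^2 =", round(x$r_squared, 4), " adj R^2 =",
      round(x$adj_r_squared, 4), " ENP =", round(x$enp, 2),
      " AICc =", round(x$aicc, 2), "\n")
  if (!is.null(x$morans))
    cat("Moran's I of std residuals =", round(x$morans$I, 4),
        " (expected", round(x$morans$expected, 4),
        ", p =", round(x$morans$p, 4), ")\n")
  invisible(x)
}

#' Select the GWR bandwidth by AICc
#'
#' Scans a log-spaced bandwidth grid between a fraction of the point-cloud
#' diameter and twice the diameter, then refines around the grid minimum
#' by golden-section search. Deterministic given the inputs. If the AICc
#' profile is not unimodal the grid minimum region is still refined and a
#' warning is emitted.
#'
#' @inheritParams fit_gwr
#' @param lower,upper Search bounds (m); defaults derived from the
#'   point-cloud diameter.
#' @param n_grid Coarse grid size.
#' @param tol Relative convergence tolerance of the golden section.
#' @return Selected bandwidth (m).
#' @export
select_bandwidth <- function(coords, y, X, kernel = "gaussian",
                             lower = NULL, upper = NULL, n_grid = 10,
                             tol = 0.01) {
  coords <- as.matrix(coords)
  D <- as.matrix(stats::dist(coords))
  diam <- max(D)
  if (diam <= 0) stop("degenerate point cloud")
  lower <- lower %||% (diam / 50)
  upper <- upper %||% (2 * diam)
  obj <- function(b) fit_gwr(coords, y, X, b, kernel, morans = FALSE)$aicc
  grid <- exp(seq(log(lower), log(upper), length.out = n_grid))
  vals <- suppressWarnings(vapply(grid, obj, numeric(1)))
  if (!any(is.finite(vals)))
    stop("AICc not finite at any candidate bandwidth")
  k <- which.min(vals)
  # unimodality check along the finite part of the grid
  fv <- vals[is.finite(vals)]
  s <- sign(diff(fv))
  s <- s[s != 0]
  if (length(s) > 1 && sum(diff(s) != 0) > 1)
    warning("AICc profile not unimodal over the grid; using global minimum")
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(n_grid, k + 1)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- suppressWarnings(obj(c1)); f2 <- suppressWarnings(obj(c2))
  while ((b - a) > tol * b) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- suppressWarnings(obj(c1))
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- suppressWarnings(obj(c2))
    }
  }
  (a + b) / 2
}

#' Moran's I with inverse-distance weights and permutation test
#'
#' Global spatial autocorrelation of `values` at `coords`, using
#' row-standardized inverse-distance weights. The expected value under no
#' autocorrelation is `-1/(n-1)`; the p-value is two-sided from a seeded
#' permutation distribution.
#'
#' @param values Numeric vector (non-constant, length >= 4).
#' @param coords Two-column matrix of locations.
#' @param nperm Number of permutations (default 999).
#' @param seed Permutation seed.
#' @return List: `I`, `expected`, `p`, `n`, `nperm`.
#' @export
morans_i <- function(values, coords, nperm = 999, seed = 1L) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 values")
  if (stats::sd(values) == 0) stop("zero variance: Moran's I undefined")
  coords <- as.matrix(coords)
  D <- as.matrix(stats::dist(coords))
  pos <- D[D > 0]
  if (length(pos) == 0L) stop("all locations coincide")
  D[D == 0] <- min(pos)   # coincident points get the nearest-pair distance
  W <- 1 / D
  diag(W) <- 0
  W <- W / rowSums(W)
  z <- values - mean(values)
  I_of <- function(zz) sum(zz * (W %*% zz)) / sum(zz^2)
  I <- I_of(z)
  set.seed(seed)
  Z <- replicate(nperm, sample(z))
  Ip <- colSums(Z * (W %*% Z)) / colSums(Z^2)
  p_hi <- (1 + sum(Ip >= I)) / (nperm + 1)
  p_lo <- (1 + sum(Ip <= I)) / (nperm + 1)
  list(I = I, expected = -1 / (n - 1), p = min(1, 2 * min(p_hi, p_lo)),
       n = n, nperm = nperm)
}
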