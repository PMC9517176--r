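test_that("constant-coefficient noiseless data reduce GWR to OLS", {
  set.seed(21)
  n <- 60
  xy <- cbind(runif(n, 0, 5000), runif(n, 0, 5000))
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 2 + 3 * X[, 1] - 1.5 * X[, 2]
  f <- fit_gwr(xy, y, X, bandwidth = 1500, morans = FALSE)
  expect_lt(max(abs(sweep(f$coefficients, 2, c(2, 3, -1.5)))), 1e-8)
  # residual identity at every location
  expect_lt(max(abs(f$fitted + f$residuals - y)), 1e-10)
})

test_that("a huge bandwidth reproduces global OLS locally", {
  set.seed(22)
  n <- 50
  xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  X <- cbind(x1 = rnorm(n))
  y <- 1 + 2 * X[, 1] + rnorm(n, 0, 0.3)
  f <- fit_gwr(xy, y, X, bandwidth = 1e6 * 1400, morans = FALSE)
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(max(abs(sweep(f$coefficients, 2, ols))), 1e-6)
})

test_that("GWR in-sample R^2 dominates OLS R^2", {
  set.seed(23)
  for (rep in 1:4) {
    n <- 40
    xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    X <- cbind(x1 = rnorm(n))
    y <- 1 + (1 + xy[, 1] / 1000) * X[, 1] + rnorm(n, 0, 0.5)
    ols_r2 <- summary(lm(y ~ X))$r.squared
    for (bw in c(200, 500, 2000)) {
      f <- fit_gwr(xy, y, X, bw, morans = FALSE)
      expect_gte(f$r_squared, ols_r2 - 1e-8)
    }
  }
})

test_that("the testbed coefficient gradient is recovered", {
  tb <- generate_gwr_testbed(200, city_config(seed = 2))
  bw <- select_bandwidth(tb$points, tb$y, tb$X)
  f <- fit_gwr(as.matrix(tb$points), tb$y, tb$X, bw, morans = FALSE)
  expect_lt(cor(f$coefficients[, "x1"], tb$points$x), -0.8)
  mae <- mean(abs(f$coefficients[, "x1"] - tb$beta_true[, 2]))
  expect_lt(mae, 0.2 * diff(range(tb$beta_true[, 2])))
})

test_that("bandwidth selection is deterministic and boundary-aware", {
  set.seed(24)
  n <- 50
  xy <- cbind(runif(n, 0, 4000), runif(n, 0, 4000))
  X <- cbind(x1 = rnorm(n))
  y <- 1 + 2 * X[, 1] + rnorm(n, 0, 0.5)   # constant coefficients
  b1 <- select_bandwidth(xy, y, X)
  b2 <- select_bandwidth(xy, y, X)
  expect_identical(b1, b2)
  # flattest model optimal: the selected fit is effectively global
  diam <- max(dist(xy))
  expect_gt(b1, 0.3 * diam)
  f <- fit_gwr(xy, y, X, b1, morans = FALSE)
  expect_lt(f$enp, 2 * (ncol(X) + 1))  # far from saturated local fits
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(max(abs(sweep(f$coefficients, 2, ols))), 0.15)
  # a strong gradient prefers a local bandwidth
  tb <- generate_gwr_testbed(120, city_config(seed = 5))
  b3 <- select_bandwidth(tb$points, tb$y, tb$X)
  expect_lt(b3, max(dist(as.matrix(tb$points))))
})

test_that("singular local designs fall back to ridge with a warning", {
  set.seed(25)
  n <- 30
  xy <- cbind(runif(n), runif(n))
  x1 <- rnorm(n)
  X <- cbind(a = x1, b = x1)   # exactly collinear
  y <- 1 + x1 + rnorm(n, 0, 0.1)
  expect_warning(f <- fit_gwr(xy, y, X, bandwidth = 0.5, morans = FALSE),
                 "ridge")
  expect_true(all(is.finite(f$fitted)))
})

test_that("Moran's I has the exact null expectation and options", {
  set.seed(26)
  xy <- cbind(runif(21), runif(21))
  m <- morans_i(rnorm(21), xy, nperm = 99)
  expect_equal(m$expected, -0.05)
  expect_error(morans_i(rep(1, 10), cbind(runif(10), runif(10))),
               "zero variance")
  # permutation p reproducible under the seed
  v <- rnorm(21)
  p1 <- morans_i(v, xy, nperm = 199, seed = 3)$p
  p2 <- morans_i(v, xy, nperm = 199, seed = 3)$p
  expect_identical(p1, p2)
})

test_that("a checkerboard pattern is negatively autocorrelated", {
  g <- expand.grid(x = 1:6, y = 1:6)
  v <- ifelse((g$x + g$y) %% 2 == 0, 1, -1)
  m <- morans_i(v, as.matrix(g), nperm = 99)
  expect_lt(m$I, m$expected)
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(27)
  n <- 25
  xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  v <- rnorm(n) + xy[, 1] / 10
  D <- as.matrix(dist(xy))
  W <- 1 / D; diag(W) <- 0; W <- W / rowSums(W)
  ours <- morans_i(v, xy, nperm = 99)
  theirs <- ape::Moran.I(v, W)
  expect_equal(ours$I, theirs$observed, tolerance = 1e-10)
  expect_equal(ours$expected, theirs$expected, tolerance = 1e-12)
})

test_that("GWR predictor selection follows the correlation rules", {
  set.seed(28)
  n <- 40
  pm <- rnorm(n)
  idx <- data.frame(
    S_div = make_cor_vec(pm, 0.8),
    H_bar = make_cor_vec(pm, 0.5),
    E_vol = make_cor_vec(pm, 0.3)
  )
  idx$L <- 0.95 * idx$S_div + sqrt(1 - 0.95^2) * make_cor_vec(pm, 0)
  out <- select_gwr_predictors(idx, pm)
  expect_equal(out[1], "S_div")
  expect_equal(out[2], "H_bar")   # strongest remaining with |r| < 0.6
  # all alternatives collinear with the first: single index + warning
  idx2 <- data.frame(a = idx$S_div, b = idx$L)
  idx2$b <- 0.99 * idx2$a + 0.01 * rnorm(n)
  expect_warning(out2 <- select_gwr_predictors(idx2, pm), "single")
  expect_length(out2, 1)
  # two weakly related indices are both returned
  idx3 <- data.frame(a = make_cor_vec(pm, 0.7), b = make_cor_vec(pm, 0.4))
  expect_length(select_gwr_predictors(idx3, pm), 2)
})
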