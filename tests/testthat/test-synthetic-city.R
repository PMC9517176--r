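test_that("panel has exactly sites x months records", {
  pan <- default_panel()
  cfg <- default_city_static()$cfg
  expect_equal(nrow(pan$panel), cfg$n_sites * cfg$n_months)
  expect_equal(length(unique(pan$panel$site_id)), cfg$n_sites)
  expect_equal(length(unique(pan$panel$month)), cfg$n_months)
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_config(seed = 7)
  p1 <- generate_parcels(cfg)
  p2 <- generate_parcels(cfg)
  expect_identical(p1, p2)
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_geojson(p1$parcels, f1); write_geojson(p2$parcels, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  m1 <- generate_meteorology(cfg); m2 <- generate_meteorology(cfg)
  expect_identical(m1, m2)
})

test_that("different seeds share the layout but differ in measurements", {
  c1 <- tiny_config(seed = 1); c2 <- tiny_config(seed = 2)
  expect_identical(generate_parcels(c1), generate_parcels(c2))
  expect_false(identical(generate_meteorology(c1)$PRE_1h,
                         generate_meteorology(c2)$PRE_1h))
  expect_false(identical(generate_buildings(c1, generate_parcels(c1))$floors,
                         generate_buildings(c2, generate_parcels(c2))$floors))
})

test_that("zero noise reproduces the truth equation to machine precision", {
  cfg <- tiny_config()
  cfg$noise_sd <- 0
  p <- generate_parcels(cfg); r <- generate_roads(cfg)
  pan <- generate_monitoring_panel(cfg, p, r)
  design <- build_design(pan$panel, pan$site_predictors)
  cf <- pan$truth$coefficients
  y0 <- cf[["(Intercept)"]] +
    as.matrix(design[, setdiff(names(cf), "(Intercept)")]) %*%
    cf[setdiff(names(cf), "(Intercept)")]
  expect_equal(pan$panel$PM25, as.numeric(y0), tolerance = 1e-12)
})

test_that("building counts track density x area and floors differ by zone", {
  tc <- tiny_city()
  b <- tc$buildings
  cand <- tc$parcels$candidates
  for (i in which(!is.na(cand$designated_type))) {
    ty <- cand$designated_type[i]
    n_b <- sum(b$zone_id == cand$cand_id[i])
    target <- tc$cfg$building_density[[ty]] * cand$area_km2[i]
    expect_lt(abs(n_b - target) / target, 0.1)
  }
  mean_fl <- tapply(b$floors, b$use_class, mean)
  expect_lt(mean_fl[["industrial"]], mean_fl[["residential"]])
  expect_lt(mean_fl[["industrial"]], mean_fl[["commercial"]])
})

test_that("footprints are pairwise disjoint", {
  tc <- tiny_city()
  b <- tc$buildings
  zid <- unique(b$zone_id)[1]
  s <- b[b$zone_id == zid, ]
  n <- nrow(s)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  w <- pmin(s$xmax[ij[, 1]], s$xmax[ij[, 2]]) -
    pmax(s$xmin[ij[, 1]], s$xmin[ij[, 2]])
  h <- pmin(s$ymax[ij[, 1]], s$ymax[ij[, 2]]) -
    pmax(s$ymin[ij[, 1]], s$ymin[ij[, 2]])
  expect_false(any(w > 0 & h > 0))
})

test_that("zone-type height distributions separate under one-way ANOVA", {
  dc <- default_city_static()
  zones <- identify_zones(dc$parcels$parcels, dc$parcels$candidates)
  idx <- landscape_indices(zones, dc$buildings)
  at <- one_way_anova(split(idx$H_bar, idx$zone_type))
  expect_lt(at$p[1], 0.05)
})

test_that("meteorology has the designed monsoon correlation structure", {
  met <- generate_meteorology(city_config(seed = 3))
  # the two true drivers are orthogonal in-sample
  expect_lt(abs(cor(met$PRE_1h, met$PRS_Sea)), 1e-10)
  # decoys load on their anchors above the screening cutoff
  expect_equal(cor(met$TEM, met$PRE_1h), 0.80, tolerance = 1e-10)
  expect_equal(cor(met$RHU, met$PRE_1h), 0.90, tolerance = 1e-10)
  expect_equal(cor(met$PRS, met$PRS_Sea), 0.97, tolerance = 1e-10)
  expect_equal(cor(met$WIN, met$PRS_Sea), 0.75, tolerance = 1e-10)
})

test_that("the GWR testbed realises its coefficient fields", {
  cfg <- tiny_config()
  tb <- generate_gwr_testbed(n = 150, config = cfg)
  expect_length(tb$y, 150)
  expect_equal(dim(tb$beta_true), c(150, 3))
  # west-east decreasing slope field
  expect_lt(cor(tb$beta_true[, 2], tb$points$x), -0.99)
  expect_gt(cor(tb$beta_true[, 3], tb$points$y), 0.99)
  # constant fields with zero noise give an exactly linear response
  tr <- synthetic_truth(cfg)
  tr$gwr_fields <- list(beta0 = c(5, 0, 0), beta1 = c(2, 0, 0),
                        beta2 = c(-1, 0, 0))
  tb0 <- generate_gwr_testbed(n = 60, config = cfg, truth = tr,
                              noise_sd = 0)
  fit <- lm(tb0$y ~ tb0$X)
  expect_equal(unname(coef(fit)), c(5, 2, -1), tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("infeasible configurations raise sizing errors", {
  cfg <- tiny_config()
  cfg$zone_areas$industrial <- c(min = 50, max = 200, mean = 100)
  expect_error(generate_parcels(cfg), "incompatible")
  cfg2 <- tiny_config()
  cfg2$building_density["residential"] <- 1e5
  p <- generate_parcels(cfg2)
  expect_error(generate_buildings(cfg2, p), "infeasible")
})
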