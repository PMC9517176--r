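test_that("height estimation uses the civil and plant floor modules", {
  expect_equal(estimate_height(10, "residential"), 28.0)
  expect_equal(estimate_height(2, "industrial"), 10.0)
  expect_equal(estimate_height(c(1, 3), c("commercial", "industrial")),
               c(2.8, 15.0))
  expect_error(estimate_height(0, "residential"), "floors")
})

test_that("height classification covers bins, gaps and extremes", {
  expect_equal(classify_height(4.0), "bungalow")
  expect_equal(classify_height(120.0), "super-high-rise")
  expect_equal(classify_height(5.6), "low-rise")   # lower edge inclusive
  expect_equal(classify_height(28.0), "high-rise") # upper edge inclusive
  # gap rule: nearest interval endpoint; |17 - 15| < |17 - 19.6|
  expect_equal(classify_height(17.0), "multistory")
  expect_equal(classify_height(18.5), "high-rise")
  # equidistant in the 5.0-5.6 gap: tie goes to the lower category
  expect_equal(classify_height(5.3), "bungalow")
  # below the first bin: nearest endpoint is 2.8
  expect_equal(classify_height(1.0), "bungalow")
  expect_error(classify_height(0), "positive")
})

test_that("every residential floor count maps to exactly one category", {
  h <- estimate_height(1:40, "residential")
  cats <- classify_height(h)
  expect_true(all(cats %in% height_categories()$category))
  expect_length(cats, 40)
})

test_that("simple indices match their definitions", {
  expect_equal(height_density(c(10, 20, 30)), 20.0)
  expect_equal(height_density(28.0), 28.0)
  expect_error(height_density(numeric(0)), "empty")
  # filled prism
  expect_equal(volume_density(1000, 10, 100), 1.0)
  expect_equal(volume_density(c(500, 500), c(10, 10), 200), 0.5)
  # population CV: sd_pop({10,30}) = 10, mean = 20
  expect_equal(spatial_dispersion(c(10, 30)), 0.5)
  expect_equal(spatial_dispersion(rep(12, 5)), 0)
  expect_equal(spatial_dispersion(28), 0)
  expect_equal(fluctuation(c(5, 30)), 25.0)
  expect_equal(fluctuation(c(2.8, 100.0)), 97.2)
  expect_equal(fluctuation(rep(9, 3)), 0)
})

test_that("diversity and uniformity follow footprint-share entropy", {
  # two categories, equal footprint area
  expect_equal(building_diversity(c(4, 25), c(100, 100)), log(2),
               tolerance = 1e-12)
  expect_equal(building_diversity(c(4, 4.5, 4.9), c(50, 70, 90)), 0)
  # shares {0.75, 0.25}
  s <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(building_diversity(c(4, 25), c(300, 100)), s,
               tolerance = 1e-12)
  expect_equal(building_uniformity(c(4, 25), c(300, 100)), 100 * s / log(2),
               tolerance = 1e-9)
  expect_equal(building_uniformity(c(4, 25), c(100, 100)), 100)
  expect_equal(building_uniformity(c(4, 4.6), c(100, 100)), 0) # one category
})

test_that("index vector matches an independent spreadsheet computation", {
  # four buildings, worked by hand:
  # heights 5.6 / 28 / 28 / 84 m; footprints 100 / 200 / 100 / 50 m^2
  b <- data.frame(height = c(5.6, 28, 28, 84),
                  fp_area = c(100, 200, 100, 50))
  iv <- index_vector(b, area = 1e4)
  expect_equal(unname(iv["H_bar"]), (5.6 + 28 + 28 + 84) / 4)
  v_tot <- 100 * 5.6 + 200 * 28 + 100 * 28 + 50 * 84
  expect_equal(unname(iv["E_vol"]), v_tot / (84 * 1e4), tolerance = 1e-12)
  m <- mean(c(5.6, 28, 28, 84))
  expect_equal(unname(iv["L"]),
               sqrt(mean((c(5.6, 28, 28, 84) - m)^2)) / m,
               tolerance = 1e-12)
  expect_equal(unname(iv["LHR"]), 84 - 5.6)
  # categories: low-rise (100), high-rise (300), high-rise-3 (50)
  p <- c(100, 300, 50) / 450
  expect_equal(unname(iv["S_div"]), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(unname(iv["E_uni"]), -sum(p * log(p)) / log(3) * 100,
               tolerance = 1e-9)
})

test_that("degenerate zone of identical buildings zeroes the spread indices", {
  b <- data.frame(height = rep(28, 5), fp_area = rep(120, 5))
  iv <- index_vector(b, area = 5e4)
  expect_equal(unname(iv[c("L", "LHR", "S_div", "E_uni")]), rep(0, 4))
  expect_error(index_vector(data.frame(height = numeric(0)), 100))
})

test_that("index invariances: translation, scaling, subdivision", {
  h <- c(6, 14, 33, 52)
  fp <- c(120, 90, 300, 150)
  # translation shifts the mean, leaves the range unchanged
  expect_equal(height_density(h + 3), height_density(h) + 3)
  expect_equal(fluctuation(h + 3), fluctuation(h))
  # scaling leaves the CV unchanged, scales mean and range
  expect_equal(spatial_dispersion(2.5 * h), spatial_dispersion(h))
  expect_equal(height_density(2.5 * h), 2.5 * height_density(h))
  expect_equal(fluctuation(2.5 * h), 2.5 * fluctuation(h))
  # splitting a building into two vertically identical halves keeps E_vol
  v1 <- volume_density(c(1200, 800), c(12, 8), 5e3)
  v2 <- volume_density(c(600, 600, 800), c(12, 12, 8), 5e3)
  expect_equal(v1, v2)
  # equal shares maximise diversity for any m >= 2
  for (m in 2:4) {
    hh <- c(4, 8, 13, 25)[seq_len(m)]
    expect_equal(building_diversity(hh, rep(50, m)), log(m),
                 tolerance = 1e-12)
    expect_equal(building_uniformity(hh, rep(50, m)), 100)
  }
})

test_that("zone-level indices satisfy the index-vector invariants", {
  tc <- tiny_city()
  zones <- identify_zones(tc$parcels$parcels, tc$parcels$candidates)
  idx <- landscape_indices(zones, tc$buildings)
  expect_true(all(idx$H_bar > 0))
  expect_true(all(idx$E_vol >= 0 & idx$E_vol < 1))
  expect_true(all(idx$E_uni >= 0 & idx$E_uni <= 100))
  expect_true(all(idx$S_div <= log(8) + 1e-12))
  expect_true(all(idx$LHR >= 0))
})
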