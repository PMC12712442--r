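test_that("thinning enforces spacing, caps, determinism and idempotence", {
  set.seed(30)
  # dense cluster: 3 points within ~1 km collapse to one
  keep <- thin_occurrences(c(0, 0.005, 0.008), c(50, 50.002, 49.999), seed = 1)
  expect_equal(length(keep), 1)
  # 500-point cloud: every kept pair is >= 10 km apart (brute force)
  lon <- runif(500, 0, 3); lat <- runif(500, 43, 46)
  k <- thin_occurrences(lon, lat, seed = 2)
  pairs <- combn(k, 2)
  d <- hav_km(lon[pairs[1, ]], lat[pairs[1, ]], lon[pairs[2, ]], lat[pairs[2, ]])
  expect_true(all(d >= 10 - 1e-9))
  # idempotent: thinning the kept set keeps everything
  k2 <- thin_occurrences(lon[k], lat[k], seed = 3)
  expect_equal(length(k2), length(k))
  # deterministic given seed
  expect_equal(thin_occurrences(lon, lat, seed = 2), k)
  # max_n cap on well-spaced points
  g <- expand.grid(lon = seq(0, 19, by = 1), lat = seq(30, 44.8, length.out = 15))
  expect_equal(length(thin_occurrences(g$lon, g$lat, max_n = 200, seed = 4)), 200)
})

test_that("grid extraction is nearest-cell with missing outside", {
  gr <- grid_from_function(function(lon, lat) lon + 100 * lat,
                           xll = 0, yll = 40, cellsize = 1, ncols = 10, nrows = 5)
  # cell centers give the cell value
  expect_equal(extract_at_points(gr, 2.5, 41.5), 2.5 + 100 * 41.5)
  expect_equal(extract_at_points(gr, 0.9, 44.2), 0.5 + 100 * 44.5)
  expect_true(is.na(extract_at_points(gr, -5, 42)))
  expect_true(is.na(extract_at_points(gr, 5, 60)))
  flat <- grid_from_function(function(lon, lat) 7 + 0 * lon,
                             0, 40, 1, 10, 5)
  expect_equal(extract_at_points(flat, runif(20, 0, 10), runif(20, 40, 45)),
               rep(7, 20))
})

test_that("grids round-trip through the plain-text format", {
  gr <- grid_from_function(function(lon, lat) round(lon * lat, 3),
                           -10, 30, 0.5, 12, 8)
  gr$values[3, 4] <- NA
  f <- tempfile(fileext = ".grid")
  write_grid(gr, f)
  rt <- read_grid(f)
  expect_equal(rt$values, gr$values)
  expect_equal(rt$cellsize, 0.5)
  expect_true(is.na(rt$values[3, 4]))
})

test_that("range percentiles match a sorted-array interpolation oracle", {
  expect_equal(range_percentile(1:100, 0.05), 5.95)
  expect_equal(range_percentile(rep(4.2, 30), 0.37), 4.2)
  expect_equal(range_percentile(3.14, 0.05), 3.14)
  set.seed(31)
  for (i in 1:200) {
    v <- rnorm(sample(2:80, 1), sd = 10)
    q <- runif(1, 0.01, 0.99)
    expect_equal(range_percentile(v, q), percentile_oracle(v, q),
                 tolerance = 1e-12)
  }
  # percentile commutes with strictly increasing transforms when it lands on
  # an order statistic (n = 41, q = 0.05 -> exactly the 3rd smallest)
  v <- rnorm(41)
  expect_equal(range_percentile(exp(v), 0.05), exp(range_percentile(v, 0.05)),
               tolerance = 1e-12)
  expect_error(range_percentile(c(NA, NA), 0.05), "non-missing")
})

test_that("maximum height prefers the model estimate, then the order statistic", {
  expect_equal(max_height_estimate(runif(500, 1, 30), model_hmax = 35)$hmax, 35)
  est <- max_height_estimate(1:150)
  expect_equal(est$hmax, 141)
  expect_equal(est$source, "order_statistic")
  few <- max_height_estimate(runif(80, 1, 30))
  expect_equal(few$source, "excluded")
  expect_match(few$reason, "fewer than 100")
  # outlier flags are honoured and order does not matter
  h <- c(1:120, 1000)
  fl <- c(rep(FALSE, 120), TRUE)
  ord <- sample(121)
  expect_equal(max_height_estimate(h[ord], fl[ord])$hmax, 111)
})

test_that("species climate summaries recover closed-form gradient truths", {
  centers <- data.frame(species = c("A a", "B b"), lon = c(-10, 10),
                        lat = c(40, 55))
  sim <- sim_occurrences_and_grids(centers, spread = 1.5, n_per_species = 300,
                                   seed = 5)
  occA <- sim$occurrences[sim$occurrences$species == "A a", ]
  s <- species_climate_summary(occA$lon, occA$lat, sim$grids, seed = 9)
  # grid cells are 0.5 deg: nearest-cell truth within half a cell of exact
  keep <- thin_occurrences(occA$lon, occA$lat, seed = 9)
  truth_tmin <- range_percentile(sim$truth$tmin_fun(occA$lon[keep], occA$lat[keep]), 0.05)
  expect_equal(s$tmin_p05, truth_tmin, tolerance = 0.5)
  # disjoint ranges order the summaries in the known direction
  occB <- sim$occurrences[sim$occurrences$species == "B b", ]
  sB <- species_climate_summary(occB$lon, occB$lat, sim$grids, seed = 9)
  expect_gt(sB$tmin_p05, s$tmin_p05)   # tmin layer increases with latitude
  expect_gt(sB$ai_p05, s$ai_p05)       # B is further east -> wetter
})
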