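test_that("EMD agrees with an exact min-cost-flow oracle on random instances", {
  set.seed(21)
  for (rep_ in 1:12) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    a <- rand_points(m); b <- rand_points(n)
    expect_equal(emd(a, b), oracle_emd_uniform(a, b), tolerance = 1e-6)
  }
})

test_that("EMD satisfies the metric axioms on uniform equal-size sets", {
  set.seed(22)
  for (rep_ in 1:6) {
    a <- rand_points(4); b <- rand_points(4); c_ <- rand_points(4)
    dab <- emd(a, b); dbc <- emd(b, c_); dac <- emd(a, c_)
    expect_gte(dab, 0)
    expect_equal(emd(a, a), 0, tolerance = 1e-9)
    expect_equal(dab, emd(b, a), tolerance = 1e-9)           # symmetry
    expect_lte(dac, dab + dbc + 1e-9)                        # triangle
    expect_gt(dab, 0)                                        # distinct sets
  }
})

test_that("singleton EMD is the Haversine distance and identical sets give 0", {
  a <- data.frame(lon = 57.78, lat = -19.85)
  b <- data.frame(lon = 63, lat = 12)
  expect_equal(emd(a, b), haversine_km(57.78, -19.85, 63, 12), tolerance = 1e-9)
  set.seed(23)
  p <- rand_points(30)
  expect_equal(emd(p, p), 0, tolerance = 1e-9)
})

test_that("meridional translation shifts EMD by the displacement", {
  set.seed(24)
  p <- rand_points(40, lon0 = 75, lat0 = -12, spread = 2)
  d_km <- 300
  q <- p; q$lat <- q$lat + d_km / 110.57  # ~300 km north
  e <- emd(p, q)
  expect_equal(e, d_km, tolerance = d_km * 0.01)
})

test_that("unequal weights are handled and mismatched totals rejected", {
  a <- data.frame(lon = c(70, 75), lat = c(-10, -12), weight = c(0.25, 0.75))
  b <- data.frame(lon = c(70, 75), lat = c(-10, -12), weight = c(0.5, 0.5))
  # optimal plan moves 0.25 mass from (75,-12) to (70,-10)
  expect_equal(emd(a, b), 0.25 * haversine_km(70, -10, 75, -12), tolerance = 1e-6)
  expect_error(gadfly:::.emd_transport(matrix(1, 2, 2), c(1, 1), c(1, 2)),
               "differ")
})

test_that("kernel UDs integrate to one and BA behaves at its extremes", {
  set.seed(25)
  p <- rand_points(25, lon0 = 80, lat0 = -15, spread = 4)
  ud <- make_ud(p, h = 200, cell_km = 50)
  expect_equal(sum(ud$p), 1, tolerance = 1e-6)
  expect_true(all(ud$p >= 0))
  expect_equal(bhattacharyya(ud, ud), 1, tolerance = 1e-9)
  # single point: a Gaussian bump integrating to 1
  ud1 <- make_ud(data.frame(lon = 80, lat = -15), h = 200, cell_km = 50)
  expect_equal(sum(ud1$p), 1, tolerance = 1e-6)
  # far-separated UDs on a shared grid overlap by < 0.01
  pa <- data.frame(lon = 55, lat = -15); pb <- data.frame(lon = 102, lat = -12)
  # ~5000 km apart
  expect_gt(haversine_km(55, -15, 102, -12), 4800)
  grid <- ud_grid(rbind(pa, pb), h = 200, cell_km = 50)
  expect_lt(bhattacharyya(make_ud(pa, 200, 50, grid), make_ud(pb, 200, 50, grid)),
            0.01)
  expect_error(bhattacharyya(ud, ud1), "different grids")
})

test_that("BA is stable under re-gridding and decreases along a transect", {
  set.seed(26)
  p <- rand_points(20, lon0 = 70, lat0 = -10, spread = 3)
  for (cell in c(50, 100)) {
    g <- ud_grid(p, h = 200, cell_km = cell)
    u1 <- make_ud(p, 200, cell, g); u2 <- make_ud(p, 200, cell, g)
    expect_gt(bhattacharyya(u1, u2), 0.999)
  }
  # monotone decay as one UD's centroid moves away
  shifts <- c(0, 2, 4, 8, 12)  # degrees of longitude
  ba <- sapply(shifts, function(s) {
    q <- p; q$lon <- q$lon + s
    g <- ud_grid(rbind(p, q), h = 200, cell_km = 50)
    bhattacharyya(make_ud(p, 200, 50, g), make_ud(q, 200, 50, g))
  })
  expect_true(all(diff(ba) < 0))
})

test_that("EMD is scale-dependent where BA saturates (the caveat)", {
  base <- data.frame(lon = c(70, 72, 74), lat = c(-10, -12, -8))
  scale_about <- function(p, f) {
    data.frame(lon = mean(p$lon) + f * (p$lon - mean(p$lon)),
               lat = mean(p$lat) + f * (p$lat - mean(p$lat)))
  }
  e1 <- emd(base, scale_about(base, 1.5))
  big <- scale_about(base, 3)
  e2 <- emd(big, scale_about(big, 1.5))
  expect_gt(e2, e1)  # larger ranges have more capacity to differ
})

test_that("period and stage splitting follow the block rules", {
  dep <- as.Date("2016-09-01"); arr <- dep + 176
  locs <- data.frame(date = rep(seq(dep, arr - 1, by = "day"), each = 2),
                     lon = runif(352, 60, 90), lat = runif(352, -20, 0))
  per <- split_periods(locs, dep, arr)
  expect_length(per, 5)  # floor(176/30), 26-day remainder dropped
  expect_equal(unname(sapply(per, nrow)), rep(60, 5))
  st <- split_stages(locs, dep, arr)
  expect_length(st, 6)
  # {30,30,29,29,29,29} days, long blocks first, spanning the whole bout
  expect_equal(unname(sapply(st, nrow)) / 2, c(30, 30, 29, 29, 29, 29))
  expect_equal(sum(sapply(st, nrow)) / 2, 176)
  expect_error(split_periods(locs[1:20, ], dep, dep + 20), "shorter")
})

test_that("pairwise comparison tables have the right structure", {
  set.seed(27)
  dep <- as.Date("2016-09-01")
  mk <- function(id, ind, shift = 0) {
    days <- seq(dep, dep + 119, by = "day")
    data.frame(track_id = id, date = days,
               lon = 70 + shift + cumsum(rnorm(120, 0, 0.1)),
               lat = -10 + cumsum(rnorm(120, 0, 0.1)))
  }
  locs <- rbind(mk("t1", "A"), mk("t2", "A"), mk("t3", "B", shift = 10))
  phen <- data.frame(track_id = c("t1", "t2", "t3"),
                     individual = c("A", "A", "B"),
                     departure_date = dep, arrival_date = dep + 120)
  w <- pairwise_comparisons(locs, phen, "whole")
  expect_equal(nrow(w), 3)  # C(3,2)
  expect_equal(sum(w$same_individual), 1)
  expect_true(all(w$emd_km >= 0))
  expect_true(all(w$ba >= 0 & w$ba <= 1))
  # within-individual pair is far more similar than cross pairs
  expect_lt(w$emd_km[w$same_individual == 1],
            min(w$emd_km[w$same_individual == 0]))
  st <- pairwise_comparisons(locs, phen, "stages")
  expect_equal(nrow(st), 6)      # one within pair x 6 stages
  expect_equal(unique(st$id1), "t1")
  expect_true(all(st$label %in% paste0("s", 1:6)))
  # identical repeated track: emd 0, ba 1
  locs2 <- rbind(mk("t1", "A"), mk("t2", "A"))
  locs2$lon[locs2$track_id == "t2"] <- locs2$lon[locs2$track_id == "t1"]
  locs2$lat[locs2$track_id == "t2"] <- locs2$lat[locs2$track_id == "t1"]
  w2 <- pairwise_comparisons(locs2, phen[1:2, ], "whole")
  expect_equal(w2$emd_km, 0, tolerance = 1e-9)
  expect_equal(w2$ba, 1, tolerance = 1e-6)
})
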