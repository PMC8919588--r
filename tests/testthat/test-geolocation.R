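test_that("twilight detection interpolates crossings and filters interference", {
  # square-wave day/night with a linear ramp; one spurious noon dip
  ts <- as.POSIXct("2016-06-01 00:00:00", tz = "UTC") + 600 * (0:(144 * 3 - 1))
  mins <- (as.numeric(ts) / 60) %% 1440
  light <- ifelse(mins >= 360 & mins < 1080, 200, 0)
  light[mins == 720] <- 0   # 1-sample shading dip at noon
  ls <- light_series(ts, light)
  tw <- detect_twilights(ls, threshold = 1)
  expect_equal(nrow(tw), 6)  # 3 days x rise+set, no spurious events
  expect_true(all(tw$kind == rep(c("rise", "set"), 3)))
  # constant darkness
  expect_warning(empty <- detect_twilights(light_series(ts, rep(0, length(ts)))),
                 "never crosses")
  expect_equal(nrow(empty), 0)
})

test_that("zenith calibration is exact noiseless and unbiased under shading", {
  lonlat <- c(57.78, -19.85)
  dates <- seq(as.Date("2016-05-20"), by = "day", length.out = 10)
  mk_tw <- function(zen, d_rise = 0, d_set = 0) {
    rise <- solar_twilight_time(lonlat[1], lonlat[2], dates, zen, "rise") + 60 * d_rise
    set <- solar_twilight_time(lonlat[1], lonlat[2], dates, zen, "set") - 60 * d_set
    out <- rbind(data.frame(time = rise, kind = "rise"),
                 data.frame(time = set, kind = "set"))
    out[order(out$time), ]
  }
  cal <- calibrate_zenith(mk_tw(96), lonlat)
  expect_equal(cal$zenith, 96, tolerance = 0.05)
  # shaded twilights, error model known: within 0.5 degrees
  set.seed(42)
  err <- replicate(5, {
    tw <- mk_tw(96, rlnorm(10, 2.2, 1), rlnorm(10, 2.2, 1))
    calibrate_zenith(tw, lonlat,
                     twilight_model = list(meanlog = 2.2, sdlog = 1))$zenith - 96
  })
  expect_lt(max(abs(err)), 0.5)
  # low-range-tag-like generating zeniths stay in their published range
  cal2 <- calibrate_zenith(mk_tw(95.5), lonlat)
  expect_gt(cal2$zenith, 94.0); expect_lt(cal2$zenith, 96.9)
  expect_error(calibrate_zenith(mk_tw(96)[1:4, ], lonlat), "3 days")
})

test_that("threshold positions invert the forward solar model", {
  # |lat| 5-35, > 30 d from an equinox: 0.5 deg lon / 1.0 deg lat
  set.seed(31)
  for (lat0 in c(-30, -15, 8, 25)) {
    for (d0 in as.Date(c("2016-06-25", "2016-12-10"))) {
      lon0 <- runif(1, 30, 110)
      dates <- seq(as.Date(d0, origin = "1970-01-01"), by = "day", length.out = 5)
      rise <- solar_twilight_time(lon0, lat0, dates, 96, "rise")
      set <- solar_twilight_time(lon0, lat0, dates, 96, "set")
      tw <- rbind(data.frame(time = rise, kind = "rise"),
                  data.frame(time = set, kind = "set"))
      tw <- tw[order(tw$time), ]
      pos <- threshold_positions(tw, 96)
      expect_lt(max(abs(pos$lon - lon0)), 0.5)
      expect_lt(max(abs(pos$lat - lat0)), 1.0)
    }
  }
})

test_that("equinox latitudes are flagged and longitudes are equivariant", {
  dates <- seq(as.Date("2016-09-18"), by = "day", length.out = 5)
  mk <- function(lon0) {
    rise <- solar_twilight_time(lon0, -20, dates, 90.2, "rise")
    set <- solar_twilight_time(lon0, -20, dates, 90.2, "set")
    tw <- rbind(data.frame(time = rise, kind = "rise"),
                data.frame(time = set, kind = "set"))
    tw[order(tw$time), ]
  }
  # at zenith ~90 day length is ~12 h for all latitudes near the equinox
  pos <- threshold_positions(mk(70), 90.2)
  expect_true(any(pos$lat_flagged))
  # +10 degrees of longitude shifts every estimate by +10
  p1 <- threshold_positions(mk(70), 96)
  p2 <- threshold_positions(mk(80), 96)
  expect_equal(p2$lon - p1$lon, rep(10, nrow(p1)), tolerance = 0.02)
  expect_error(threshold_positions(data.frame(
    time = dates[1:2], kind = c("rise", "rise")), 96), "alternate")
})

test_that("MCMC refinement keeps samples off land and respects the speed prior", {
  sc <- make_refinement_scenario(seed = 7)
  mask <- read_land_mask()
  init <- threshold_positions(sc$twilights, sc$zenith)
  post <- refine_track_mcmc(init, sc$twilights, sc$calibration,
                            mask = mask, field = sc$field, sst = sc$sst,
                            control = fast_mcmc, seed = 5)
  sub <- seq(1, nrow(post$lon), by = 10)
  expect_equal(sum(on_land(as.vector(post$lon[sub, ]),
                           as.vector(post$lat[sub, ]), mask)), 0)
  med <- summarize_posterior(post)
  # shrinkage: posterior speeds no larger than the noisy threshold track's
  sp <- function(lon, lat, t) {
    haversine_km(lon[-length(lon)], lat[-length(lat)], lon[-1], lat[-1]) /
      pmax(diff(as.numeric(t)) / 3600, 0.5)
  }
  expect_lt(mean(sp(med$lon, med$lat, med$time)),
            mean(sp(init$lon, init$lat, init$time)))
  # credible intervals bracket the median
  expect_true(all(med$lon_lo <= med$lon & med$lon <= med$lon_hi))
  expect_true(all(med$lat_lo <= med$lat & med$lat <= med$lat_hi))
})

test_that("widening the SST likelihood widens latitude credible intervals", {
  sc <- make_refinement_scenario(seed = 8)
  init <- threshold_positions(sc$twilights, sc$zenith)
  width <- sapply(c(0.5, 4), function(sd_) {
    post <- refine_track_mcmc(init, sc$twilights, sc$calibration,
                              mask = read_land_mask(), field = sc$field,
                              sst = sc$sst,
                              control = c(fast_mcmc, list(sst_sd = sd_)),
                              seed = 6)
    med <- summarize_posterior(post)
    mean(med$lat_hi - med$lat_lo)
  })
  expect_gt(width[2], width[1])
})

test_that("posterior summaries are chain-permutation invariant and use nearest ranks", {
  sc <- make_refinement_scenario(seed = 9)
  init <- threshold_positions(sc$twilights, sc$zenith)
  post <- refine_track_mcmc(init, sc$twilights, sc$calibration,
                            mask = read_land_mask(), field = sc$field,
                            sst = sc$sst, control = fast_mcmc, seed = 7)
  s1 <- summarize_posterior(post)
  # relabel chains (move chain 1's block to the end)
  n1 <- sum(post$chain == 1)
  perm <- c(seq_len(nrow(post$lon))[-(1:n1)], 1:n1)
  post2 <- post
  post2$lon <- post$lon[perm, ]; post2$lat <- post$lat[perm, ]
  expect_identical(summarize_posterior(post2)[c("lon", "lat", "lon_lo", "lat_hi")],
                   s1[c("lon", "lat", "lon_lo", "lat_hi")])
  # nearest-rank percentiles: 2.5% of 12000 retained -> order statistic 300
  x <- sample(seq_len(12000))
  post_toy <- list(lon = matrix(x, 12000, 1), lat = matrix(x, 12000, 1),
                   epochs = data.frame(time = post$epochs$time[1],
                                       date = post$epochs$date[1],
                                       kind = "rise"))
  s_toy <- summarize_posterior(post_toy)
  expect_equal(s_toy$lon_lo, 300)
  expect_equal(s_toy$lon_hi, 11700)
  # degenerate posterior: zero-width intervals
  post3 <- post
  post3$lon[] <- 70; post3$lat[] <- -10
  s3 <- summarize_posterior(post3)
  expect_true(all(s3$lon_hi - s3$lon_lo == 0))
})
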