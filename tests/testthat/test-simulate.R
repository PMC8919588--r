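cfg_small <- function(...) {
  sim_config(n_individuals = 4, years_per_individual = 2, ...)
}

test_that("population simulation is deterministic and carries ground truth", {
  mask <- read_land_mask()
  p1 <- simulate_population(cfg_small(), seed = 7, mask = mask)
  p2 <- simulate_population(cfg_small(), seed = 7, mask = mask)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$tracks[[3]]$positions, p2$tracks[[3]]$positions)
  expect_equal(nrow(p1$truth), 8)
  expect_equal(p1$R_true_departure, 20^2 / (20^2 + 10^2))  # 0.8 by construction
  tr <- p1$tracks[[1]]
  expect_lt(tr$departure_day, tr$arrival_day)
  expect_equal(tr$duration, tr$arrival_day - tr$departure_day)
  # ashore days sit at the colony; at-sea days are off land
  d <- tr$daily
  expect_true(all(d$lon[d$state == "ashore"] == 57.78))
  expect_false(any(on_land(d$lon[d$state == "atsea"], d$lat[d$state == "atsea"], mask)))
})

test_that("study-scale defaults give 131 tracks from 62 individuals", {
  cfg <- sim_config()
  expect_equal(cfg$n_individuals, 62)
  expect_equal(sum(cfg$years_per_individual), 131)
})

test_that("consecutive positions respect a speed cap", {
  p <- simulate_population(cfg_small(), seed = 8)
  for (tr in p$tracks[1:2]) {
    ep <- tr$positions
    d <- haversine_km(ep$lon[-nrow(ep)], ep$lat[-nrow(ep)], ep$lon[-1], ep$lat[-1])
    dt <- diff(as.numeric(ep$time)) / 3600
    expect_lt(max(d / dt), 80)
  }
})

test_that("variance components of simulated departures match the configuration", {
  # n = 500 individuals x 2 years; empirical components within 10%
  cfg <- sim_config(n_individuals = 500, years_per_individual = 2)
  set.seed(99)
  mu <- rnorm(500, cfg$mean_departure_day, cfg$sd_between)
  dep <- round(rep(mu, each = 2) + rnorm(1000, 0, cfg$sd_within))
  gid <- rep(seq_len(500), each = 2)
  gm <- tapply(dep, gid, mean)
  msw <- sum((dep - gm[gid])^2) / 500
  msb <- 2 * sum((gm - mean(dep))^2) / 499
  expect_equal(msw, cfg$sd_within^2, tolerance = 0.1)
  expect_equal((msb - msw) / 2, cfg$sd_between^2, tolerance = 0.1)
  # and the generator itself reproduces the same law (smaller n, wider check)
  p <- simulate_population(sim_config(n_individuals = 120, years_per_individual = 2),
                           seed = 5)
  t <- p$truth
  gm <- tapply(t$departure_day, t$individual, mean)
  msw2 <- sum((t$departure_day - gm[t$individual])^2) / 120
  expect_equal(sqrt(msw2), cfg$sd_within, tolerance = 0.2)
})

test_that("unreachable destinations and degenerate durations error", {
  cfg <- cfg_small()
  mask <- read_land_mask()
  expect_error(simulate_track(cfg, "x", 2015, 100, 20, c(100, -20), mask),
               "unreachable")
  expect_error(simulate_track(cfg, "x", 2015, 100, 1, c(63, 12), mask),
               "duration")
  # destination on land rejected at the population level
  cfg_bad <- cfg_small(destinations = data.frame(name = "india", lon = 78,
                                                 lat = 20, prob = 1))
  expect_error(simulate_population(cfg_bad, seed = 1), "on land")
})

test_that("rendered light separates ashore shading from at-sea days", {
  cfg <- cfg_small(shading_ashore = 0.9, shading_atsea = 0.1)
  p <- simulate_population(cfg, seed = 11)
  tr <- p$tracks[[1]]
  set.seed(2)
  lt <- render_light(tr, cfg)
  tp <- tag_params(cfg$tag_model)
  day <- as.Date(lt$timestamp)
  st <- tr$daily$state[match(day, tr$daily$date)]
  daylight <- lt$light > 0
  interf <- lt$light < tp$interference_threshold & daylight
  p_ashore <- sum(interf[st == "ashore"]) / sum(daylight[st == "ashore"])
  p_atsea <- sum(interf[st == "atsea"]) / sum(daylight[st == "atsea"])
  expect_gt(p_ashore, 0.8)   # ~0.9 by construction
  expect_lt(p_atsea, 0.25)
  # full-range tag: unshaded daytime values reach >= 100
  expect_gte(max(lt$light), 100)
})

test_that("noiseless rendering lets twilight detection recover truth", {
  cfg <- cfg_small(twilight_noise = FALSE, shading_ashore = 0, shading_atsea = 0)
  p <- simulate_population(cfg, seed = 12)
  tr <- p$tracks[[1]]
  lt <- render_light(tr, cfg)
  tw <- detect_twilights(lt)
  truth <- gadfly:::.true_twilights(tr, cfg$zenith)
  m <- match(as.Date(tw$time[tw$kind == "rise"]), truth$date)
  err <- as.numeric(tw$time[tw$kind == "rise"] - truth$rise[m], units = "mins")
  expect_lt(max(abs(err), na.rm = TRUE), 10)  # within one sampling bin
})

test_that("immersion and SST renderers match their observation models", {
  cfg <- cfg_small(wet_rate_ashore = 0, wet_rate_atsea = 0.5)
  p <- simulate_population(cfg, seed = 13)
  tr <- p$tracks[[1]]
  set.seed(3)
  im <- render_immersion(tr, cfg)
  day <- as.Date(im$timestamp)
  st <- tr$daily$state[match(day, tr$daily$date)]
  wet_daily <- tapply(im$wet_count, day, sum)
  st_daily <- tr$daily$state[match(names(wet_daily), as.character(tr$daily$date))]
  expect_equal(unname(wet_daily[st_daily == "ashore"][1]), 0)  # dry ashore
  # at-sea: 144 intervals x 20 x 0.5 ~ 1440
  expect_equal(mean(wet_daily[st_daily == "atsea"]), 144 * 20 * 0.5,
               tolerance = 0.05)
  # SST: zero-noise log equals the field exactly at the true position
  cfg0 <- cfg_small(sst_noise_sd = 0)
  field <- synthetic_sst_field()
  sst <- render_sst(tr, field, cfg0)
  i <- 25
  d <- as.Date(sst$timestamp[i])
  pos <- tr$daily[tr$daily$date == d, ]
  expect_equal(sst$temp_c[i], sst_at(field, pos$lon, pos$lat, d), tolerance = 1e-9)
})
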