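# small labelled feature table: nd days with a known ashore/at-sea truth
make_features <- function(states, seed = 1, sep = 3) {
  set.seed(seed)
  nd <- length(states)
  at <- states == "atsea"
  data.frame(
    date = as.Date("2016-06-01") + seq_len(nd) - 1,
    interference_count = rbinom(nd, 60, ifelse(at, 0.15, 0.85)),
    daylight_sample_count = rep(60L, nd),
    wet_sum = round(pmax(0, rnorm(nd, ifelse(at, 1400, 30), 150 / sep))),
    colony_distance_km = pmax(0, rnorm(nd, ifelse(at, 2000, 15), 300 / sep)))
}

test_that("daily features reflect the simulated observation model", {
  cfg <- sim_config(n_individuals = 1, years_per_individual = 1,
                    shading_ashore = 0.9, shading_atsea = 0.1)
  p <- simulate_population(cfg, seed = 3)
  tr <- p$tracks[[1]]
  set.seed(4)
  lt <- render_light(tr, cfg)
  im <- render_immersion(tr, cfg)
  twl <- gadfly:::.true_twilights(tr, cfg$zenith)
  tw <- rbind(data.frame(time = twl$rise, kind = "rise"),
              data.frame(time = twl$set, kind = "set"))
  tw <- tw[order(tw$time), ]
  track <- data.frame(date = tr$daily$date, lon = tr$daily$lon, lat = tr$daily$lat)
  f <- daily_features(lt, im, track, cfg$colony, tw)
  f <- f[!is.na(f$interference_count), ]
  ashore <- tr$daily$state[match(f$date, tr$daily$date)] == "ashore"
  p_int <- f$interference_count / f$daylight_sample_count
  expect_gt(mean(p_int[ashore]), 0.8)
  expect_lt(mean(p_int[!ashore]), 0.3)
  expect_true(all(f$wet_sum[ashore] < 200))
  expect_true(all(f$colony_distance_km[ashore] < 50))
  # at-sea distance agrees with the WGS84 geodesic of the truth position
  i <- which(!ashore)[20]
  d <- tr$daily[tr$daily$date == f$date[i], ]
  expect_equal(f$colony_distance_km[i],
               geodesic_m(cfg$colony[1], cfg$colony[2], d$lon, d$lat) / 1000,
               tolerance = 1e-6)
  # all daytime samples above the interference threshold -> zero count
  lt2 <- lt; lt2$light[] <- 150
  f2 <- daily_features(lt2, im, track, cfg$colony, tw)
  expect_true(all(f2$interference_count == 0, na.rm = TRUE))
})

test_that("EM log-likelihood is monotone and the fit recovers separated states", {
  states <- rep(c("ashore", "atsea", "ashore"), c(60, 120, 60))
  f <- make_features(states, seed = 5)
  m <- fit_hmm(f, seed = 2)
  expect_true(all(diff(m$loglik_trace) > -1e-7))
  dec <- decode_states(m, f)
  expect_gte(mean(dec$state == states), 0.98)
  expect_equal(rowSums(cbind(dec$p_ashore, dec$p_atsea)), rep(1, nrow(f)),
               tolerance = 1e-12)
})

test_that("forward-backward and Viterbi match exhaustive enumeration on toys", {
  for (seed in 1:3) {
    states <- sample(c("ashore", "atsea"), 8, replace = TRUE)
    f <- make_features(states, seed = seed, sep = 1)
    m <- fit_hmm(make_features(rep(c("ashore", "atsea"), each = 40), seed = seed), seed = 1)
    le <- gadfly:::.hmm_logemiss(m, f)
    fb <- gadfly:::.hmm_forward_backward(log(m$pi), log(m$A), le)
    oracle <- oracle_hmm_enumerate(log(m$pi), log(m$A), le)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-10)
    dec <- decode_states(m, f)
    expect_equal(match(dec$state, c("ashore", "atsea")), unname(oracle$viterbi))
  }
})

test_that("decoding is invariant to affine rescaling of Gaussian features", {
  states <- rep(c("ashore", "atsea", "ashore"), c(70, 110, 60))
  f <- make_features(states, seed = 6)
  f2 <- f
  f2$colony_distance_km <- f2$colony_distance_km * 1000  # metres, say
  m1 <- fit_hmm(f, seed = 3); m2 <- fit_hmm(f2, seed = 3)
  expect_identical(decode_states(m1, f)$state, decode_states(m2, f2)$state)
})

test_that("missing features are marginalised, not imputed", {
  states <- rep(c("ashore", "atsea", "ashore"), c(60, 120, 60))
  f <- make_features(states, seed = 7)
  f$colony_distance_km[100:110] <- NA
  f$interference_count[50:55] <- NA
  m <- fit_hmm(f, seed = 4)
  dec <- decode_states(m, f)
  expect_equal(nrow(dec), nrow(f))        # rows retained
  expect_gte(mean(dec$state == states), 0.95)
})

test_that("migration extraction applies the three-month rule exactly", {
  mk_states <- function(run) {
    data.frame(date = as.Date("2016-06-01") + 0:(60 + run + 59),
               state = rep(c("ashore", "atsea", "ashore"), c(60, run, 60)))
  }
  expect_equal(nrow(extract_migrations(mk_states(89))), 0)  # 89 d: rejected
  m90 <- extract_migrations(mk_states(90))                  # 90 d: accepted
  expect_equal(nrow(m90), 1)
  expect_equal(m90$duration, 90)
  expect_false(m90$partial)
  expect_equal(m90$arrival_date - m90$departure_date, as.difftime(90, units = "days"))
  m100 <- extract_migrations(mk_states(100))
  expect_equal(m100$duration, 100)
  expect_equal(m100$departure_date, as.Date("2016-06-01") + 60)
  # runs touching the record edge are flagged partial
  st <- data.frame(date = as.Date("2016-06-01") + 0:199,
                   state = rep(c("atsea", "ashore"), c(120, 80)))
  expect_true(extract_migrations(st)$partial)
  # duration identity across the petrel-year boundary
  st2 <- data.frame(date = as.Date("2017-01-01") + 0:299,
                    state = rep(c("ashore", "atsea", "ashore"), c(50, 200, 50)))
  m2 <- extract_migrations(st2)
  expect_equal(m2$duration, 200)
  expect_equal(m2$departure_season, "summer")
})
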