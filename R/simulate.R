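## Synthetic petrel populations with known ground truth. Individuals get a
## latent mean departure day and migration duration (between-individual
## variance) realised with within-individual noise each year, a non-breeding
## destination reused across years with high probability, and an
## out-and-back great-circle movement with residency at the destination.
## Raw logger series (light with shading, immersion, SST) are rendered from
## the truth so that every downstream stage can be tested against it.

#' Simulation configuration
#'
#' Defaults describe the study system: 62 individuals tracked over 2-4
#' petrel years (131 tracks), population mean departure around day 120 of
#' the petrel year with 20 d between- and 10 d within-individual SD (true
#' departure repeatability 0.8), migrations lasting on average 175 d
#' (between/within SDs 19/20 d, true duration repeatability ~0.47),
#' destinations spread across the tropical Indianian Ocean basin and
#' reused across years with probability 0.9, cruising speed 20 km/h, and
#' the twilight shading error model log-normal(meanlog 2.2, sdlog 1.0)
#' minutes.
#'
#' @param n_individuals number of individuals.
#' @param years_per_individual integer vector recycled over individuals
#'   (default: the study's 57x2, 3x3, 2x4 pattern when `n_individuals`
#'   is 62, otherwise 2 years each).
#' @param mean_departure_day,sd_between,sd_within departure-day model
#'   (days; day 1 = 1 June).
#' @param duration_mean,duration_sd_between,duration_sd_within migration
#'   duration model (days).
#' @param min_duration migrations are truncated below at this length.
#' @param destinations matrix/data.frame of destination centroids
#'   (`lon`, `lat`) with assignment probabilities `prob`.
#' @param reuse_prob probability an individual reuses last year's
#'   destination.
#' @param speed_kmh cruising speed for outbound/inbound travel.
#' @param dest_jitter_km SD of day-to-day residency scatter about the
#'   destination centroid.
#' @param zenith solar zenith angle (deg) at the tag's light threshold.
#' @param twilight_meanlog,twilight_sdlog log-normal shading delay
#'   (log-minutes) applied to rendered twilights (sunrise delayed, sunset
#'   advanced); set `twilight_noise = FALSE` for noiseless rendering.
#' @param twilight_noise logical.
#' @param shading_ashore,shading_atsea per-sample probability a daytime
#'   light reading is shaded below the interference threshold.
#' @param wet_rate_ashore,wet_rate_atsea per-test immersion probability.
#' @param sst_noise_sd logger SST noise SD (deg C).
#' @param tag_model see [tag_params()].
#' @param colony `c(lon, lat)` of the colony.
#' @param start_year first petrel year (calendar year of its 1 June).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 62,
                       years_per_individual = NULL,
                       mean_departure_day = 120,
                       sd_between = 20, sd_within = 10,
                       duration_mean = 175,
                       duration_sd_between = 19, duration_sd_within = 20,
                       min_duration = 95,
                       destinations = NULL,
                       reuse_prob = 0.9,
                       speed_kmh = 20,
                       dest_jitter_km = 150,
                       zenith = 96,
                       twilight_meanlog = 2.2, twilight_sdlog = 1.0,
                       twilight_noise = TRUE,
                       shading_ashore = 0.9, shading_atsea = 0.15,
                       wet_rate_ashore = 0.02, wet_rate_atsea = 0.5,
                       sst_noise_sd = 0.5,
                       tag_model = "full-range",
                       colony = c(57.78, -19.85),
                       start_year = 2014) {
  if (is.null(years_per_individual)) {
    years_per_individual <- if (n_individuals == 62) {
      c(rep(2L, 57), rep(3L, 3), rep(4L, 2))
    } else 2L
  }
  if (is.null(destinations)) {
    destinations <- data.frame(
      name = c("somali_basin", "arabian_sea", "central_io", "bay_of_bengal", "waus_basin"),
      lon = c(52, 63, 80, 87, 100),
      lat = c(0, 12, -12, 10, -20),
      prob = c(0.25, 0.25, 0.25, 0.1, 0.15))
  }
  stopifnot(sd_between >= 0, sd_within >= 0, speed_kmh > 0,
            all(destinations$prob >= 0),
            shading_ashore >= 0, shading_ashore <= 1,
            shading_atsea >= 0, shading_atsea <= 1)
  cfg <- list(n_individuals = n_individuals,
              years_per_individual = rep_len(as.integer(years_per_individual), n_individuals),
              mean_departure_day = mean_departure_day,
              sd_between = sd_between, sd_within = sd_within,
              duration_mean = duration_mean,
              duration_sd_between = duration_sd_between,
              duration_sd_within = duration_sd_within,
              min_duration = min_duration,
              destinations = destinations, reuse_prob = reuse_prob,
              speed_kmh = speed_kmh, dest_jitter_km = dest_jitter_km,
              zenith = zenith,
              twilight_meanlog = twilight_meanlog, twilight_sdlog = twilight_sdlog,
              twilight_noise = twilight_noise,
              shading_ashore = shading_ashore, shading_atsea = shading_atsea,
              wet_rate_ashore = wet_rate_ashore, wet_rate_atsea = wet_rate_atsea,
              sst_noise_sd = sst_noise_sd, tag_model = tag_model,
              colony = colony, start_year = start_year)
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic weekly SST field
#'
#' A smooth, zonally structured field with a mild seasonal cycle on the
#' product's native 1 x 1 degree weekly layout, standing in for remotely
#' sensed optimum-interpolation SST. The meridional gradient (~0.5 deg C
#' per degree latitude in the study window) is what lets logger SST inform
#' latitude near the equinoxes.
#'
#' @param lons,lats grid vectors (degrees, 1-degree spacing).
#' @return an [sst_field()].
#' @export
synthetic_sst_field <- function(lons = 20:130, lats = -45:30) {
  weeks <- 1:52
  a <- array(0, c(length(lons), length(lats), length(weeks)))
  for (w in weeks) {
    seas <- 1.5 * cos(2 * pi * (w - 5) / 52)
    lat_term <- 28.5 - 0.012 * (outer(rep(1, length(lons)), lats) - 5)^2
    lon_term <- 0.3 * sin(outer(lons, rep(1, length(lats))) * pi / 45)
    a[, , w] <- lat_term + lon_term + seas * outer(rep(1, length(lons)), -lats / 45)
  }
  sst_field(lons, lats, weeks, pmax(a, -1.8))
}

## great-circle interpolation between two lon/lat points (fractions f in [0,1])
.gc_interp <- function(p1, p2, f) {
  to_xyz <- function(p) {
    phi <- .deg2rad(p[2]); lam <- .deg2rad(p[1])
    c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  }
  a <- to_xyz(p1); b <- to_xyz(p2)
  omega <- acos(min(1, max(-1, sum(a * b))))
  if (omega < 1e-12) {
    return(data.frame(lon = rep(p1[1], length(f)), lat = rep(p1[2], length(f))))
  }
  sa <- sin((1 - f) * omega) / sin(omega); sb <- sin(f * omega) / sin(omega)
  x <- sa * a[1] + sb * b[1]; y <- sa * a[2] + sb * b[2]; z <- sa * a[3] + sb * b[3]
  data.frame(lon = .rad2deg(atan2(y, x)), lat = .rad2deg(asin(pmin(1, pmax(-1, z)))))
}

## km offset -> degrees at a latitude
.km_to_deg <- function(km_east, km_north, lat) {
  cbind(km_east / (111.32 * cos(.deg2rad(lat))), km_north / 110.57)
}

#' Simulate one migration track (truth)
#'
#' Out-and-back great-circle movement: outbound travel to the destination
#' at the configured cruising speed, day-to-day residency scatter (AR(1))
#' around the destination centroid with rejection against the land mask,
#' and an inbound leg; ashore days sit exactly at the colony. Two position
#' epochs per day (~06:00 and ~18:00 local).
#'
#' @param config a [sim_config()].
#' @param individual_id,year identifiers (year = petrel-year start year).
#' @param departure_day,duration day index of departure (from 1 June) and
#'   migration length in days.
#' @param destination `c(lon, lat)`.
#' @param mask a `land_mask`.
#' @return list of class `truth_track`.
#' @export
simulate_track <- function(config, individual_id, year, departure_day, duration,
                           destination, mask) {
  if (duration < 2) stop("simulate_track: duration below minimum")
  colony <- config$colony
  dist <- haversine_km(colony[1], colony[2], destination[1], destination[2])
  t_leg <- ceiling(dist / (config$speed_kmh * 24))
  if (2 * t_leg + 3 > duration) {
    stop("simulate_track: destination unreachable within the migration duration at the configured speed")
  }
  arrival_day <- departure_day + duration
  n_days <- max(365, arrival_day + 14)
  origin <- as.Date(paste0(year, "-06-01"))
  dates <- origin + (seq_len(n_days) - 1L)
  state <- ifelse(seq_len(n_days) >= departure_day & seq_len(n_days) < arrival_day,
                  "atsea", "ashore")
  res_days <- duration - 2 * t_leg
  # daily AR(1) residency scatter, land-rejected
  lonlat <- matrix(NA_real_, n_days, 2)
  prev <- c(0, 0)
  rho <- 0.7; innov_sd <- config$dest_jitter_km * sqrt(1 - rho^2)
  for (d in seq_len(n_days)) {
    td <- d - departure_day  # 0-based at-sea day
    if (state[d] == "ashore") {
      lonlat[d, ] <- colony
    } else if (td < t_leg) {
      lonlat[d, ] <- as.numeric(.gc_interp(colony, destination, (td + 0.5) / t_leg))
    } else if (td >= duration - t_leg) {
      back <- (td - (duration - t_leg) + 0.5) / t_leg
      lonlat[d, ] <- as.numeric(.gc_interp(destination, colony, back))
    } else {
      for (try in 1:50) {
        prop <- rho * prev + stats::rnorm(2, 0, innov_sd)
        off <- .km_to_deg(prop[1], prop[2], destination[2])
        cand <- c(destination[1] + off[1], destination[2] + off[2])
        if (!on_land(cand[1], cand[2], mask)) break
      }
      prev <- prop
      lonlat[d, ] <- cand
    }
  }
  # epochs: ~06:00 and ~18:00 local solar time, small within-day scatter
  ut_off <- (-colony[1] / 15) %% 24
  ep <- data.frame(
    date = rep(dates, each = 2L),
    epoch = rep(1:2, n_days),
    time = rep(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC"), each = 2L) +
      3600 * (rep(c(6, 18), n_days) + ut_off),
    lon = rep(lonlat[, 1], each = 2L),
    lat = rep(lonlat[, 2], each = 2L))
  # sub-daily scatter at sea (a few km) so consecutive epochs are distinct
  at <- rep(state == "atsea", each = 2L)
  if (any(at)) {
    off <- .km_to_deg(stats::rnorm(sum(at), 0, 15), stats::rnorm(sum(at), 0, 15),
                      ep$lat[at])
    ep$lon[at] <- ep$lon[at] + off[, 1]
    ep$lat[at] <- ep$lat[at] + off[, 2]
  }
  structure(list(individual_id = individual_id, year = year,
                 departure_day = departure_day, arrival_day = arrival_day,
                 departure_date = origin + departure_day - 1L,
                 arrival_date = origin + arrival_day - 1L,
                 duration = duration, destination = destination,
                 daily = data.frame(date = dates, state = state,
                                    lon = lonlat[, 1], lat = lonlat[, 2]),
                 positions = ep),
            class = "truth_track")
}

#' Simulate a population of repeat-tracked petrels
#'
#' Individual i's departure in year y is Normal(mu_i, sd_within) with
#' mu_i ~ Normal(mean_departure_day, sd_between), so the true departure
#' repeatability sd_between^2/(sd_between^2+sd_within^2) is known by
#' construction (and likewise for duration). Destinations are drawn from
#' the configured centroid set and reused across an individual's years
#' with probability `reuse_prob`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (all randomness is derived from it).
#' @param mask a `land_mask` (default: the shipped coarse mask).
#' @return list of class `sim_population`: `tracks` (list of
#'   `truth_track`), `individuals` (latent parameters), `truth` (one row
#'   per track: individual, year, departure/arrival day, duration,
#'   destination), `R_true_departure`, `R_true_duration`, `config`.
#' @export
simulate_population <- function(config = sim_config(), seed = 1,
                                mask = read_land_mask()) {
  set.seed(seed)
  dest <- config$destinations
  if (any(on_land(dest$lon, dest$lat, mask))) {
    stop("simulate_population: a configured destination centroid is on land")
  }
  tracks <- list(); truth <- list(); ind_par <- list()
  for (i in seq_len(config$n_individuals)) {
    id <- sprintf("bird%03d", i)
    mu_dep <- stats::rnorm(1, config$mean_departure_day, config$sd_between)
    mu_dur <- stats::rnorm(1, config$duration_mean, config$duration_sd_between)
    d_idx <- sample.int(nrow(dest), 1, prob = dest$prob)
    ind_par[[i]] <- data.frame(individual = id, mu_departure = mu_dep,
                               mu_duration = mu_dur, first_destination = dest$name[d_idx])
    ny <- config$years_per_individual[i]
    for (y in seq_len(ny)) {
      if (y > 1 && stats::runif(1) > config$reuse_prob) {
        d_idx <- sample.int(nrow(dest), 1, prob = dest$prob)
      }
      dep <- round(stats::rnorm(1, mu_dep, config$sd_within))
      dep <- max(dep, 10L)
      dur <- round(stats::rnorm(1, mu_dur, config$duration_sd_within))
      dur <- max(dur, config$min_duration)
      yr <- config$start_year + y - 1L
      tr <- simulate_track(config, id, yr, dep, dur,
                           c(dest$lon[d_idx], dest$lat[d_idx]), mask)
      tracks[[length(tracks) + 1L]] <- tr
      truth[[length(truth) + 1L]] <- data.frame(
        track_id = sprintf("%s_%d", id, yr), individual = id, year = yr,
        departure_day = tr$departure_day, arrival_day = tr$arrival_day,
        departure_date = tr$departure_date, arrival_date = tr$arrival_date,
        duration = tr$duration,
        dest_lon = dest$lon[d_idx], dest_lat = dest$lat[d_idx],
        destination = dest$name[d_idx])
    }
  }
  r_of <- function(sb, sw) sb^2 / (sb^2 + sw^2)
  structure(list(tracks = tracks,
                 truth = do.call(rbind, truth),
                 individuals = do.call(rbind, ind_par),
                 R_true_departure = r_of(config$sd_between, config$sd_within),
                 R_true_duration = r_of(config$duration_sd_between, config$duration_sd_within),
                 config = config),
            class = "sim_population")
}

## true twilight times for each day of a track, at the day's first/second
## epoch position; returns data.frame(date, rise, set)
.true_twilights <- function(track, zenith) {
  ep <- track$positions
  e1 <- ep[ep$epoch == 1, ]; e2 <- ep[ep$epoch == 2, ]
  data.frame(
    date = e1$date,
    rise = solar_twilight_time(e1$lon, e1$lat, e1$date, zenith, "rise"),
    set = solar_twilight_time(e2$lon, e2$lat, e2$date, zenith, "set"))
}

#' Render raw logger series from a truth track
#'
#' `render_light()` builds the 10-min maximum-light series: light ramps up
#' at the (shading-delayed) observed sunrise and down at the (advanced)
#' observed sunset; each daytime sample is independently shaded below the
#' tag's interference threshold with the state-dependent probability
#' (ashore >> at sea). `render_immersion()` draws per-interval wet counts
#' Binomial(max_per_interval, rate_state). `render_sst()` samples the SST
#' field at the true position (4/day at sea) plus Gaussian noise.
#'
#' @param track a `truth_track`.
#' @param config the [sim_config()] used to simulate it.
#' @return a [light_series()] / [immersion_series()] / [sst_log()].
#' @export
render_light <- function(track, config) {
  tp <- tag_params(config$tag_model)
  twl <- .true_twilights(track, config$zenith)
  n_days <- nrow(twl)
  if (config$twilight_noise) {
    d_rise <- stats::rlnorm(n_days, config$twilight_meanlog, config$twilight_sdlog)
    d_set <- stats::rlnorm(n_days, config$twilight_meanlog, config$twilight_sdlog)
  } else {
    d_rise <- d_set <- rep(0, n_days)
  }
  rise_obs <- twl$rise + 60 * d_rise
  set_obs <- twl$set - 60 * d_set
  t0 <- as.POSIXct(paste(twl$date[1], "00:00:00"), tz = "UTC")
  ts <- t0 + seq(0, by = 600, length.out = n_days * 144L)
  day_of <- findInterval(as.numeric(ts), as.numeric(as.POSIXct(paste(twl$date, "00:00:00"), tz = "UTC")))
  ramp <- 1800  # light ramps over 30 min around the threshold crossings
  tn <- as.numeric(ts)
  up <- (tn - as.numeric(rise_obs)[day_of]) / ramp
  dn <- (as.numeric(set_obs)[day_of] - tn) / ramp
  frac <- pmin(1, pmax(0, pmin(up, dn)))
  light <- tp$light_day * frac
  # shading of daytime samples
  st <- track$daily$state[day_of]
  p_shade <- ifelse(st == "ashore", config$shading_ashore, config$shading_atsea)
  shaded <- stats::runif(length(ts)) < p_shade & frac > 0.5
  light[shaded] <- stats::runif(sum(shaded), 0, tp$interference_threshold * 0.9)
  light_series(ts, light, config$tag_model)
}

#' @rdname render_light
#' @export
render_immersion <- function(track, config) {
  tp <- tag_params(config$tag_model)
  dates <- track$daily$date
  n <- length(dates) * 144L
  t0 <- as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC")
  ts <- t0 + seq(0, by = 600, length.out = n)  # interval-start labels
  st <- rep(track$daily$state, each = 144L)
  rate <- ifelse(st == "ashore", config$wet_rate_ashore, config$wet_rate_atsea)
  wet <- stats::rbinom(n, tp$wet_max, rate)
  immersion_series(ts, wet, config$tag_model)
}

#' @rdname render_light
#' @param field an [sst_field()].
#' @export
render_sst <- function(track, field, config) {
  d <- track$daily
  at <- d$state == "atsea"
  if (!any(at)) {
    return(sst_log(as.POSIXct(character(), tz = "UTC"), numeric(0)))
  }
  dates <- rep(d$date[at], each = 4L)
  hours <- rep(c(2, 8, 14, 20), sum(at))
  ts <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC") + 3600 * hours
  temp <- sst_at(field, rep(d$lon[at], each = 4L), rep(d$lat[at], each = 4L), dates) +
    stats::rnorm(length(ts), 0, config$sst_noise_sd)
  sst_log(ts, pmin(pmax(temp, -1.9), 39.9))
}

#' Simulated calibration twilights at a known location
#'
#' Twilight times over a pre-deployment calibration window at the colony,
#' generated at the configured zenith, optionally with the log-normal
#' shading delays (tags are typically exposed during calibration, so the
#' default is clean).
#'
#' @param config a [sim_config()].
#' @param start first calibration date.
#' @param n_days window length (3-5 days).
#' @param noisy apply the shading error model (default FALSE).
#' @return data.frame `time`, `kind` (a twilight series).
#' @export
simulate_calibration <- function(config, start = as.Date(paste0(config$start_year, "-05-20")),
                                 n_days = 5, noisy = FALSE) {
  dates <- as.Date(start) + seq_len(n_days) - 1L
  rise <- solar_twilight_time(config$colony[1], config$colony[2], dates, config$zenith, "rise")
  set <- solar_twilight_time(config$colony[1], config$colony[2], dates, config$zenith, "set")
  if (noisy) {
    rise <- rise + 60 * stats::rlnorm(n_days, config$twilight_meanlog, config$twilight_sdlog)
    set <- set - 60 * stats::rlnorm(n_days, config$twilight_meanlog, config$twilight_sdlog)
  }
  times <- c(rise, set)
  kind <- rep(c("rise", "set"), each = n_days)
  ord <- order(times)
  data.frame(time = times[ord], kind = kind[ord])
}
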