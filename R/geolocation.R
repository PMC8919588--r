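## Threshold light-level geolocation: twilight detection, zenith
## calibration, initial threshold positions, and Bayesian (MCMC) track
## refinement under twilight-error / flight-speed / land-mask / SST models.

#' Detect twilight events in a light series
#'
#' Sunrise = upward crossing of the light threshold, sunset = downward.
#' Crossing times are interpolated linearly within the 10-min sampling
#' bin. Light/dark runs shorter than `min_run_hours` (e.g. a one-sample
#' shading dip at noon) are treated as interference and merged into their
#' neighbours, which also enforces sunrise/sunset alternation.
#'
#' @param light a [light_series()].
#' @param threshold light threshold; default from the series' tag model
#'   (4 low-range, 1 full-range).
#' @param min_run_hours minimum credible day/night length (default 4 h).
#' @return data.frame `time`, `kind` (`"rise"`/`"set"`), with the
#'   threshold in attribute `"threshold"`. Zero rows (with a warning) if
#'   the light never crosses the threshold.
#' @export
detect_twilights <- function(light, threshold = NULL, min_run_hours = 4) {
  if (is.null(threshold)) {
    threshold <- tag_params(attr(light, "tag_model"))$light_threshold
  }
  lit <- light$light >= threshold
  if (all(lit) || all(!lit)) {
    warning("detect_twilights: light never crosses the threshold")
    return(structure(data.frame(time = light$timestamp[0], kind = character(0)),
                     threshold = threshold))
  }
  min_run <- max(1L, round(min_run_hours * 6))  # samples at 10-min cadence
  repeat {
    r <- rle(lit)
    inner <- which(r$lengths < min_run)
    inner <- inner[inner > 1 & inner < length(r$lengths)]
    if (!length(inner)) break
    # flip the shortest spurious run
    k <- inner[which.min(r$lengths[inner])]
    i0 <- sum(r$lengths[seq_len(k - 1)]) + 1L
    lit[i0:(i0 + r$lengths[k] - 1L)] <- !r$values[k]
  }
  tr <- which(diff(lit) != 0)  # boundary between sample i and i+1
  if (!length(tr)) {
    warning("detect_twilights: no transitions after filtering")
    return(structure(data.frame(time = light$timestamp[0], kind = character(0)),
                     threshold = threshold))
  }
  t1 <- light$timestamp[tr]; t2 <- light$timestamp[tr + 1L]
  v1 <- light$light[tr]; v2 <- light$light[tr + 1L]
  f <- (threshold - v1) / (v2 - v1)
  f[!is.finite(f)] <- 0.5
  f <- pmin(1, pmax(0, f))
  structure(data.frame(time = t1 + f * as.numeric(t2 - t1, units = "secs"),
                       kind = ifelse(lit[tr + 1L], "rise", "set")),
            threshold = threshold)
}

#' Calibrate the solar zenith angle at a known location
#'
#' With no twilight error model, the zenith is the value at which the
#' median discrepancy between observed and predicted twilight times over
#' the calibration window is zero (exact for clean twilights). When the
#' shading error model is known (`twilight_model = list(meanlog, sdlog)`,
#' log-minutes), the calibration instead maximises the one-sided
#' log-normal likelihood of the delays, which removes the systematic bias
#' the median estimator would absorb into the zenith (the median shading
#' delay exp(meanlog) is ~9 min for the default model, worth ~2 deg of
#' zenith).
#'
#' @param twilights data.frame `time`, `kind` from [detect_twilights()]
#'   or [simulate_calibration()].
#' @param lonlat known calibration location `c(lon, lat)`.
#' @param twilight_model `NULL` or `list(meanlog=, sdlog=)`.
#' @param zenith_range search interval in degrees.
#' @return list of class `calibration_result`: `zenith`, fitted `meanlog`
#'   / `sdlog` of the residual delays, and the residuals (minutes) at the
#'   chosen zenith.
#' @export
calibrate_zenith <- function(twilights, lonlat, twilight_model = NULL,
                             zenith_range = c(91, 107)) {
  days <- unique(as.Date(twilights$time))
  if (length(days) < 3) stop("calibrate_zenith: need at least 3 days of twilights")
  resid_min <- function(z) {
    pred <- solar_twilight_time(lonlat[1], lonlat[2], as.Date(twilights$time),
                                z, twilights$kind)
    r <- as.numeric(twilights$time - pred, units = "mins")
    ifelse(twilights$kind == "rise", r, -r)  # shading delay, minutes
  }
  if (is.null(twilight_model)) {
    f <- function(z) stats::median(resid_min(z))
    zen <- stats::uniroot(f, zenith_range, tol = 1e-5)$root
  } else {
    ml <- twilight_model$meanlog; sl <- twilight_model$sdlog
    nll <- function(z) {
      r <- resid_min(z)
      if (any(r <= 0)) return(1e10)
      -sum(stats::dlnorm(r, ml, sl, log = TRUE))
    }
    # support boundary: smallest zenith with all delays positive
    zen <- stats::optimize(nll, zenith_range, tol = 1e-5)$minimum
  }
  r <- resid_min(zen)
  pos <- r[r > 0]
  structure(list(zenith = zen,
                 meanlog = if (length(pos) > 1) mean(log(pos)) else NA_real_,
                 sdlog = if (length(pos) > 1) stats::sd(log(pos)) else NA_real_,
                 residuals = r),
            class = "calibration_result")
}

#' Initial positions by the threshold method
#'
#' For each consecutive twilight pair, longitude follows from the twilight
#' midpoint versus solar noon/midnight (equation-of-time corrected) and
#' latitude from the day (or night) length given the solar declination and
#' the calibrated zenith. Near the equinoxes day length is ~12 h at every
#' latitude; unsolvable latitudes are flagged and imputed by interpolation
#' from neighbouring epochs.
#'
#' @param twilights data.frame `time`, `kind` (alternating).
#' @param zenith calibrated zenith angle, degrees.
#' @return data.frame `time` (pair midpoint), `date`, `lon`, `lat`,
#'   `lat_flagged` (TRUE where imputed).
#' @export
threshold_positions <- function(twilights, zenith) {
  n <- nrow(twilights)
  if (n < 2) stop("threshold_positions: need at least one twilight pair")
  if (any(twilights$kind[-1] == twilights$kind[-n])) {
    stop("threshold_positions: twilight kinds must alternate")
  }
  k1 <- twilights$kind[-n]
  t1 <- twilights$time[-n]; t2 <- twilights$time[-1]
  tmid <- t1 + as.numeric(t2 - t1, units = "secs") / 2
  sp <- solar_position(tmid)
  mins <- (as.numeric(tmid) / 60) %% 1440
  half_deg <- as.numeric(t2 - t1, units = "mins") / 8  # half-interval in degrees
  is_day <- k1 == "rise"
  # longitude: apparent solar time at midpoint is 12:00 (day pair) / 00:00
  lon_raw <- ifelse(is_day, (720 - sp$eqtime - mins) / 4,
                    (1440 - sp$eqtime - mins) / 4)
  lon <- ((lon_raw + 180) %% 360) - 180
  h_deg <- ifelse(is_day, half_deg, 180 - half_deg)
  dec <- .deg2rad(sp$declination)
  a <- sin(dec); b <- cos(dec) * cos(.deg2rad(h_deg))
  rr <- sqrt(a^2 + b^2); psi <- atan2(b, a)
  s <- cos(.deg2rad(zenith)) / rr
  # a sin(phi) + b cos(phi) = cos(zenith) has two roots; keep the physical one
  wrap <- function(x) ((x + 180) %% 360) - 180
  phi1 <- wrap(.rad2deg(asin(pmin(1, pmax(-1, s))) - psi))
  phi2 <- wrap(180 - .rad2deg(asin(pmin(1, pmax(-1, s)))) - .rad2deg(psi))
  ok1 <- abs(phi1) <= 89; ok2 <- abs(phi2) <= 89
  lat <- ifelse(ok1 & (!ok2 | abs(phi1) <= abs(phi2)), phi1,
                ifelse(ok2, phi2, NA))
  flagged <- abs(s) > 1 | (!ok1 & !ok2)
  lat[flagged] <- NA
  if (all(is.na(lat))) {
    lat[] <- 0; # wholly indeterminate window: fall back to equator
  } else if (anyNA(lat)) {
    idx <- seq_along(lat)
    lat <- stats::approx(idx[!is.na(lat)], lat[!is.na(lat)], idx, rule = 2)$y
  }
  data.frame(time = tmid, date = as.Date(tmid), lon = lon, lat = lat,
             lat_flagged = flagged)
}

## per-twilight quantities the sampler needs (closed-form prediction:
## r = A + q*4*lon + 4*H(lat))
.twilight_model_terms <- function(twilights) {
  sp <- solar_position(twilights$time)
  day0 <- as.POSIXct(paste(as.Date(twilights$time), "00:00:00"), tz = "UTC")
  obs_min <- as.numeric(twilights$time) / 60
  noon0 <- as.numeric(day0) / 60 + 720 - sp$eqtime  # solar noon at lon 0
  q <- ifelse(twilights$kind == "rise", 1, -1)
  list(A = q * (obs_min - noon0), q = q, dec = .deg2rad(sp$declination))
}

#' Refine a threshold track by MCMC (Estelle-style model)
#'
#' Metropolis-within-Gibbs over per-twilight locations. The log target
#' sums (i) a one-sided log-normal density of the twilight delay in
#' minutes (shading can only delay sunrise / advance sunset), (ii) a
#' gamma density of the great-circle speed between consecutive locations,
#' (iii) a Gaussian SST likelihood matching daily median logger SST to a
#' gridded weekly field (bilinear in space, nearest week), and (iv) a
#' land mask (probability 0 on land). The schedule is: burn-in
#' with relaxed assumptions (speed-prior rate halved, mask softened to a
#' penalty) and proposal-scale tuning; three short runs to
#' check split-chain Rhat < 1.1 on lon/lat (burn-in extended on failure);
#' then `n_chains` retained chains.
#'
#' @param initial data.frame from [threshold_positions()].
#' @param twilights data.frame `time`, `kind`.
#' @param calibration a `calibration_result` (or list with `zenith`); the
#'   twilight error model defaults to its fitted `meanlog`/`sdlog` unless
#'   overridden in `control`.
#' @param movement_prior list `shape`, `rate` of the gamma flight-speed
#'   prior (km/h scale).
#' @param mask a `land_mask`.
#' @param field an [sst_field()], or NULL to drop the SST term.
#' @param sst a [sst_log()] from the tag, or NULL.
#' @param control list: `burn` (2000), `conv_len` (300), `conv_reps` (3),
#'   `n_chains` (4), `chain_len` (3000), `thin` (20: sweeps per retained
#'   sample; sample counts follow the stated schedule, thinning is a
#'   mixing/autocorrelation choice), `rhat_max` (1.1), `max_restarts` (3),
#'   `sst_sd` (1.0), `meanlog`, `sdlog`, `mask_penalty` (20),
#'   `strict` (TRUE: error on non-convergence).
#' @param seed integer seed.
#' @return object of class `posterior_track`: retained samples
#'   (`lon`, `lat`: iterations x twilights, with `chain` labels), the
#'   twilight epochs, acceptance rates, and `rhat`.
#' @export
refine_track_mcmc <- function(initial, twilights, calibration,
                              movement_prior = list(shape = 2, rate = 0.1),
                              mask = read_land_mask(),
                              field = NULL, sst = NULL,
                              control = list(), seed = 1) {
  ctl <- utils::modifyList(list(burn = 2000, conv_len = 300, conv_reps = 3,
                                n_chains = 4, chain_len = 3000, thin = 20,
                                rhat_max = 1.1, max_restarts = 3,
                                sst_sd = 1.0, meanlog = NULL, sdlog = NULL,
                                mask_penalty = 20, strict = TRUE), control)
  meanlog <- if (!is.null(ctl$meanlog)) ctl$meanlog else calibration$meanlog
  sdlog <- if (!is.null(ctl$sdlog)) ctl$sdlog else calibration$sdlog
  if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog <= 0) {
    meanlog <- 2.2; sdlog <- 1.0  # conservative default shading prior
  }
  K <- nrow(twilights)
  tm <- .twilight_model_terms(twilights)
  dt_h <- diff(as.numeric(twilights$time)) / 3600
  dt_h <- pmax(dt_h, 0.5)
  # map initial pair positions onto twilights (twilight k bounds pairs k-1,k)
  init_lon <- stats::approx(seq_len(K - 1) + 0.5, initial$lon, seq_len(K), rule = 2)$y
  init_lat <- stats::approx(seq_len(K - 1) + 0.5, initial$lat, seq_len(K), rule = 2)$y
  set.seed(seed)
  init_lon <- init_lon + stats::rnorm(K, 0, 0.2)
  init_lat <- pmin(85, pmax(-85, init_lat + stats::rnorm(K, 0, 0.2)))
  # daily median logger SST per twilight date
  sst_obs <- rep(NA_real_, K)
  wk <- rep(1L, K)
  if (!is.null(field)) {
    dts <- as.Date(twilights$time)
    wk <- pmin((as.integer(format(dts, "%j")) - 1L) %/% 7L + 1L, max(field$weeks))
    wk <- match(wk, field$weeks)
    wk[is.na(wk)] <- 1L
    if (!is.null(sst) && nrow(sst) > 0) {
      med <- tapply(sst$temp_c, as.Date(sst$timestamp), stats::median)
      m <- match(as.character(dts), names(med))
      sst_obs <- as.numeric(med[m])
    }
  }
  fgrid <- if (!is.null(field)) {
    c(field$lons[1], field$lons[2] - field$lons[1], length(field$lons),
      field$lats[1], field$lats[2] - field$lats[1], length(field$lats))
  } else c(0, 1, 2, 0, 1, 2)
  ftemp <- if (!is.null(field)) as.numeric(field$temp) else rep(25, 2 * 2 * 1)
  if (is.null(field)) { sst_obs <- rep(NA_real_, K); wk <- rep(1L, K) }
  px <- unlist(lapply(mask, function(r) r[, 1]))
  py <- unlist(lapply(mask, function(r) r[, 2]))
  rl <- vapply(mask, nrow, 1L)
  rs <- c(0L, cumsum(rl)[-length(rl)])
  run <- function(lon, lat, scales, n, relax, adapt, collect, thin = 1L) {
    .estelle_run(lon, lat, tm$A, tm$q, tm$dec, calibration$zenith,
                 meanlog, sdlog, dt_h,
                 movement_prior$shape,
                 if (relax) movement_prior$rate / 2 else movement_prior$rate,
                 sst_obs, as.integer(wk - 1L), ftemp, fgrid, ctl$sst_sd,
                 px, py, as.integer(rs), as.integer(rl),
                 !relax, ctl$mask_penalty,
                 scales, as.integer(n), adapt, collect, as.integer(thin))
  }
  scales <- rep(1, K)
  state <- list(lon = init_lon, lat = init_lat)
  rhat <- Inf
  for (attempt in seq_len(ctl$max_restarts + 1L)) {
    b <- run(state$lon, state$lat, scales, ctl$burn, relax = TRUE,
             adapt = TRUE, collect = FALSE)
    scales <- b$scales
    # hard-mask settle with continued tuning so the full model's proposal
    # scales are calibrated before convergence is assessed
    b2 <- run(b$lon, b$lat, scales, 300, relax = FALSE, adapt = TRUE, collect = FALSE)
    scales <- b2$scales
    state <- list(lon = b2$lon, lat = b2$lat)
    # three consecutive short runs from the same chain; split-chain Rhat
    # across them checks stationarity
    conv <- vector("list", ctl$conv_reps)
    for (cc in seq_len(ctl$conv_reps)) {
      conv[[cc]] <- run(state$lon, state$lat, scales, ctl$conv_len,
                        relax = FALSE, adapt = FALSE, collect = TRUE,
                        thin = ctl$thin)
      state <- list(lon = conv[[cc]]$lon, lat = conv[[cc]]$lat)
    }
    rhat <- max(.split_rhat(lapply(conv, `[[`, "lon_samples")),
                .split_rhat(lapply(conv, `[[`, "lat_samples")))
    if (is.finite(rhat) && rhat < ctl$rhat_max) break
    ctl$burn <- ctl$burn + 1000
  }
  converged <- is.finite(rhat) && rhat < ctl$rhat_max
  if (!converged && ctl$strict) {
    stop(sprintf("refine_track_mcmc: split-chain Rhat %.3f >= %.2f after %d restarts",
                 rhat, ctl$rhat_max, ctl$max_restarts))
  }
  chains <- lapply(seq_len(ctl$n_chains), function(cc) {
    run(state$lon, state$lat, scales, ctl$chain_len,
        relax = FALSE, adapt = FALSE, collect = TRUE, thin = ctl$thin)
  })
  lon_s <- do.call(rbind, lapply(chains, `[[`, "lon_samples"))
  lat_s <- do.call(rbind, lapply(chains, `[[`, "lat_samples"))
  acc <- Reduce(`+`, lapply(chains, `[[`, "acc")) /
    (ctl$n_chains * ctl$chain_len * ctl$thin)
  structure(list(lon = lon_s, lat = lat_s,
                 chain = rep(seq_len(ctl$n_chains), each = ctl$chain_len),
                 epochs = data.frame(time = twilights$time,
                                     date = as.Date(twilights$time),
                                     kind = twilights$kind),
                 acc_rate = acc, rhat = rhat, converged = converged,
                 zenith = calibration$zenith,
                 meanlog = meanlog, sdlog = sdlog),
            class = "posterior_track")
}

## split-chain Rhat, max over columns; chains: list of iteration x K matrices
.split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch) %/% 2
    halves <- c(halves, list(ch[seq_len(n), , drop = FALSE],
                             ch[n + seq_len(n), , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)                       # K x m
  vars <- sapply(halves, function(h) apply(h, 2, stats::var))
  bvar <- n * apply(means, 1, stats::var)
  wvar <- rowMeans(vars)
  wvar <- pmax(wvar, 1e-12)
  max(sqrt(((n - 1) / n * wvar + bvar / n) / wvar))
}

#' Summarise a posterior track to medians and 95% credible intervals
#'
#' Componentwise median and 2.5/97.5 percentiles (nearest-rank) per
#' twilight epoch, i.e. two summarised positions per day.
#'
#' @param post a `posterior_track`.
#' @return data.frame `time, date, kind, lon, lat, lon_lo, lon_hi,
#'   lat_lo, lat_hi`.
#' @export
summarize_posterior <- function(post) {
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), type = 1, names = FALSE)
  ql <- apply(post$lon, 2, qs); qt <- apply(post$lat, 2, qs)
  data.frame(time = post$epochs$time, date = post$epochs$date,
             kind = post$epochs$kind,
             lon = ql[2, ], lat = qt[2, ],
             lon_lo = ql[1, ], lon_hi = ql[3, ],
             lat_lo = qt[1, ], lat_hi = qt[3, ])
}
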