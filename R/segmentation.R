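## Daily behavioural features, two-state (ashore / at-sea) hidden Markov
## model fitted by EM (Baum-Welch), Viterbi decoding, and extraction of
## migration bouts and phenology dates.

#' Daily behavioural features from raw series and the estimated track
#'
#' Three features per calendar day: (1) the proportion of daytime light
#' samples with interference (value below the tag's interference
#' threshold) within the twilight-to-twilight window minus a margin
#' (shading indicates a bird sitting ashore); (2) the daily sum of the 144
#' ten-minute wet counts (ashore birds stay dry); (3) the distance from
#' the colony (km, WGS84 geodesic) of the day's median position estimate.
#' Days missing a component keep their row with that feature `NA`.
#'
#' @param light a [light_series()]; `immersion` an [immersion_series()].
#' @param immersion an [immersion_series()].
#' @param track data.frame with `date`, `lon`, `lat` (e.g. from
#'   [summarize_posterior()]).
#' @param colony `c(lon, lat)`.
#' @param twilights data.frame `time`, `kind` used to bound the daylight
#'   window.
#' @param tag_model see [tag_params()].
#' @param margin_min margin trimmed off each end of the daylight window
#'   (minutes, default 30) to isolate core daylight hours.
#' @return data.frame `date, interference_count, daylight_sample_count,
#'   wet_sum, colony_distance_km`.
#' @export
daily_features <- function(light, immersion, track, colony, twilights,
                           tag_model = attr(light, "tag_model"),
                           margin_min = 30) {
  thr <- tag_params(tag_model)$interference_threshold
  dates <- sort(unique(c(as.Date(light$timestamp), as.Date(immersion$timestamp))))
  # first rise and following set per date
  twd <- split(twilights, as.Date(twilights$time))
  ldate <- as.Date(light$timestamp)
  idate <- as.Date(immersion$timestamp)
  wet_by_day <- tapply(immersion$wet_count, idate, sum)
  tr_by_day <- split(track[, c("lon", "lat")], as.Date(track$date))
  light_idx <- split(seq_len(nrow(light)), ldate)
  out <- data.frame(date = dates, interference_count = NA_integer_,
                    daylight_sample_count = NA_integer_,
                    wet_sum = NA_real_, colony_distance_km = NA_real_)
  for (r in seq_along(dates)) {
    d <- as.character(dates[r])
    tw <- twd[[d]]
    if (!is.null(tw)) {
      rise <- tw$time[tw$kind == "rise"][1]
      sets <- tw$time[tw$kind == "set"]
      set <- sets[sets > rise][1]
      if (!is.na(rise) && !is.na(set)) {
        w0 <- rise + margin_min * 60; w1 <- set - margin_min * 60
        cand <- light_idx[[d]]
        sel <- cand[light$timestamp[cand] >= w0 & light$timestamp[cand] <= w1]
        out$daylight_sample_count[r] <- length(sel)
        out$interference_count[r] <- sum(light$light[sel] < thr)
      }
    }
    if (d %in% names(wet_by_day)) out$wet_sum[r] <- wet_by_day[[d]]
    tp <- tr_by_day[[d]]
    if (!is.null(tp) && nrow(tp) > 0) {
      out$colony_distance_km[r] <- geodesic_m(colony[1], colony[2],
                                              stats::median(tp$lon),
                                              stats::median(tp$lat)) / 1000
    }
  }
  out
}

## log-emission matrix (days x 2 states); missing features marginalised out
.hmm_logemiss <- function(model, feats) {
  nd <- nrow(feats)
  le <- matrix(0, nd, 2)
  d <- (feats$colony_distance_km - model$scale$dist_c) / model$scale$dist_s
  w <- (feats$wet_sum - model$scale$wet_c) / model$scale$wet_s
  for (s in 1:2) {
    t1 <- stats::dnorm(d, model$dist_mean[s], model$dist_sd[s], log = TRUE)
    t2 <- stats::dnorm(w, model$wet_mean[s], model$wet_sd[s], log = TRUE)
    t3 <- stats::dbinom(feats$interference_count, feats$daylight_sample_count,
                        model$interf_p[s], log = TRUE)
    t1[is.na(t1)] <- 0; t2[is.na(t2)] <- 0; t3[is.na(t3)] <- 0
    le[, s] <- t1 + t2 + t3
  }
  le
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## forward-backward in log space (two states, recursions inlined for speed);
## returns loglik, gamma (posteriors), xi sums
.hmm_forward_backward <- function(logpi, logA, le) {
  nd <- nrow(le)
  la <- matrix(0, nd, 2); lb <- matrix(0, nd, 2)
  lse2 <- function(p, q) { m <- pmax(p, q); m + log1p(exp(pmin(p, q) - m)) }
  a11 <- logA[1, 1]; a12 <- logA[1, 2]; a21 <- logA[2, 1]; a22 <- logA[2, 2]
  f1 <- logpi[1] + le[1, 1]; f2 <- logpi[2] + le[1, 2]
  la[1, 1] <- f1; la[1, 2] <- f2
  for (t in 2:nd) {
    n1 <- lse2(f1 + a11, f2 + a21) + le[t, 1]
    n2 <- lse2(f1 + a12, f2 + a22) + le[t, 2]
    f1 <- n1; f2 <- n2
    la[t, 1] <- f1; la[t, 2] <- f2
  }
  b1 <- 0; b2 <- 0
  for (t in (nd - 1):1) {
    e1 <- le[t + 1, 1] + b1; e2 <- le[t + 1, 2] + b2
    n1 <- lse2(a11 + e1, a12 + e2)
    n2 <- lse2(a21 + e1, a22 + e2)
    b1 <- n1; b2 <- n2
    lb[t, 1] <- b1; lb[t, 2] <- b2
  }
  ll <- lse2(la[nd, 1], la[nd, 2])
  gamma <- exp(la + lb - ll)
  h <- seq_len(nd - 1)
  eb1 <- le[h + 1, 1] + lb[h + 1, 1]; eb2 <- le[h + 1, 2] + lb[h + 1, 2]
  xi <- matrix(c(sum(exp(la[h, 1] + a11 + eb1 - ll)),
                 sum(exp(la[h, 2] + a21 + eb1 - ll)),
                 sum(exp(la[h, 1] + a12 + eb2 - ll)),
                 sum(exp(la[h, 2] + a22 + eb2 - ll))), 2, 2)
  list(loglik = ll, gamma = gamma, xi = xi)
}

#' Fit the two-state ashore/at-sea hidden Markov model
#'
#' Emissions are Gaussian for colony distance and daily wet sum
#' (standardised internally) and Binomial for the interference count given
#' the day's daylight sample count, conditionally independent given the
#' state. Fitted by EM (Baum-Welch) to a relative log-likelihood tolerance
#' of 1e-6 (max 500 iterations), best of `n_restarts` random starts.
#' States are canonicalised so state 1 ("ashore") has the smaller mean
#' distance.
#'
#' @param feats a [daily_features()] table (>= 60 days).
#' @param n_restarts random restarts (default 3).
#' @param seed integer seed.
#' @param max_iter,tol EM stopping rule.
#' @return list of class `hmm_model` with initial probabilities,
#'   transition matrix, emission parameters, scaling constants,
#'   `loglik_trace` of the winning run.
#' @export
fit_hmm <- function(feats, n_restarts = 3, seed = 1, max_iter = 500, tol = 1e-6) {
  if (nrow(feats) < 60) stop("fit_hmm: need at least 60 days of features")
  set.seed(seed)
  sc <- list(dist_c = mean(feats$colony_distance_km, na.rm = TRUE),
             dist_s = max(stats::sd(feats$colony_distance_km, na.rm = TRUE), 1e-6),
             wet_c = mean(feats$wet_sum, na.rm = TRUE),
             wet_s = max(stats::sd(feats$wet_sum, na.rm = TRUE), 1e-6))
  d <- (feats$colony_distance_km - sc$dist_c) / sc$dist_s
  w <- (feats$wet_sum - sc$wet_c) / sc$wet_s
  best <- NULL
  for (r in seq_len(n_restarts)) {
    q <- stats::runif(1, 0.3, 0.7)
    model <- list(pi = c(0.5, 0.5),
                  A = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE),
                  dist_mean = stats::quantile(d, c(q * 0.5, 0.5 + q * 0.5), na.rm = TRUE, names = FALSE),
                  dist_sd = c(1, 1) * stats::runif(1, 0.5, 1.5),
                  wet_mean = stats::quantile(w, c(q * 0.5, 0.5 + q * 0.5), na.rm = TRUE, names = FALSE),
                  wet_sd = c(1, 1),
                  interf_p = sort(stats::runif(2, 0.05, 0.95), decreasing = TRUE),
                  scale = sc)
    trace <- numeric(0)
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      le <- .hmm_logemiss(model, feats)
      fb <- .hmm_forward_backward(log(model$pi), log(model$A), le)
      trace <- c(trace, fb$loglik)
      g <- fb$gamma
      model$pi <- pmax(g[1, ], 1e-10); model$pi <- model$pi / sum(model$pi)
      A <- fb$xi / pmax(rowSums(fb$xi), 1e-300)
      model$A <- pmin(pmax(A, 1e-8), 1 - 1e-8)
      model$A <- model$A / rowSums(model$A)
      for (s in 1:2) {
        gv <- g[, s]
        okd <- !is.na(d); okw <- !is.na(w)
        model$dist_mean[s] <- sum(gv[okd] * d[okd]) / sum(gv[okd])
        # SD floor (0.01 on the standardised scale): an exactly constant
        # feature -- e.g. ashore distance from truth positions -- must not
        # collapse the Gaussian emission
        model$dist_sd[s] <- max(0.01,
          sqrt(sum(gv[okd] * (d[okd] - model$dist_mean[s])^2) / sum(gv[okd])))
        model$wet_mean[s] <- sum(gv[okw] * w[okw]) / sum(gv[okw])
        model$wet_sd[s] <- max(0.01,
          sqrt(sum(gv[okw] * (w[okw] - model$wet_mean[s])^2) / sum(gv[okw])))
        oki <- !is.na(feats$interference_count) & !is.na(feats$daylight_sample_count) &
          feats$daylight_sample_count > 0
        p <- sum(gv[oki] * feats$interference_count[oki]) /
          sum(gv[oki] * feats$daylight_sample_count[oki])
        model$interf_p[s] <- min(max(p, 1e-6), 1 - 1e-6)
      }
      pars <- c(model$dist_mean, model$dist_sd, model$wet_mean, model$wet_sd,
                model$interf_p)
      if (any(!is.finite(pars))) { ok <- FALSE; break }  # degenerate: restart
      if (it > 1 && abs(trace[it] - trace[it - 1]) <
          tol * (abs(trace[it - 1]) + 1e-12)) break
    }
    if (!ok) next
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- c(model, list(loglik = trace[length(trace)], loglik_trace = trace))
    }
  }
  if (is.null(best)) stop("fit_hmm: all restarts degenerate")
  # canonicalise: state 1 = ashore = smaller mean distance
  if (best$dist_mean[1] > best$dist_mean[2]) {
    sw <- function(x) x[2:1]
    best$pi <- sw(best$pi); best$A <- best$A[2:1, 2:1]
    best$dist_mean <- sw(best$dist_mean); best$dist_sd <- sw(best$dist_sd)
    best$wet_mean <- sw(best$wet_mean); best$wet_sd <- sw(best$wet_sd)
    best$interf_p <- sw(best$interf_p)
  }
  class(best) <- "hmm_model"
  best
}

#' Decode daily behavioural states
#'
#' Viterbi maximum a-posteriori path plus per-day posterior state
#' probabilities (forward-backward); missing features are marginalised.
#'
#' @param model a fitted [fit_hmm()] model.
#' @param feats a [daily_features()] table.
#' @return data.frame `date, state` (`"ashore"`/`"atsea"`), `p_ashore`,
#'   `p_atsea`.
#' @export
decode_states <- function(model, feats) {
  le <- .hmm_logemiss(model, feats)
  nd <- nrow(le)
  logA <- log(model$A)
  # Viterbi
  v <- matrix(-Inf, nd, 2); ptr <- matrix(1L, nd, 2)
  v[1, ] <- log(model$pi) + le[1, ]
  for (t in 2:nd) {
    for (s in 1:2) {
      cand <- v[t - 1, ] + logA[, s]
      ptr[t, s] <- which.max(cand)
      v[t, s] <- cand[ptr[t, s]] + le[t, s]
    }
  }
  path <- integer(nd)
  path[nd] <- which.max(v[nd, ])
  for (t in (nd - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  fb <- .hmm_forward_backward(log(model$pi), logA, le)
  data.frame(date = feats$date,
             state = c("ashore", "atsea")[path],
             p_ashore = fb$gamma[, 1], p_atsea = fb$gamma[, 2])
}

#' Extract migration bouts and phenology from a decoded state sequence
#'
#' A migration is a maximal run of at-sea days lasting at least
#' `min_days` (three months), bounded by ashore days on both sides; runs
#' touching the start/end of the record are flagged `partial` and should
#' be excluded from phenology statistics. Departure is the first at-sea
#' day, arrival the first ashore day after the run, duration their
#' difference in days (calendar-aware).
#'
#' @param states data.frame `date`, `state` from [decode_states()].
#' @param min_days minimum migration length (default 90).
#' @return data.frame `departure_date, arrival_date, duration,
#'   departure_day, arrival_day, departure_season, arrival_season,
#'   partial` (possibly 0 rows).
#' @export
extract_migrations <- function(states, min_days = 90) {
  r <- rle(states$state == "atsea")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_days) next
    dep <- states$date[starts[k]]
    partial <- starts[k] == 1L || ends[k] == nrow(states)
    arr <- if (ends[k] < nrow(states)) states$date[ends[k] + 1L] else states$date[ends[k]] + 1L
    out[[length(out) + 1L]] <- data.frame(
      departure_date = dep, arrival_date = arr,
      duration = as.integer(arr - dep),
      departure_day = day_index(dep), arrival_day = day_index(arr),
      departure_season = season_of(dep), arrival_season = season_of(arr),
      partial = partial)
  }
  if (!length(out)) {
    return(data.frame(departure_date = as.Date(character()),
                      arrival_date = as.Date(character()),
                      duration = integer(), departure_day = integer(),
                      arrival_day = integer(), departure_season = character(),
                      arrival_season = character(), partial = logical()))
  }
  do.call(rbind, out)
}
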