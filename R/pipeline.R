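## Stage orchestration: simulate -> geolocate -> segment -> similarity ->
## stats. Each stage is a pure function of its inputs plus a seed derived
## deterministically from the pipeline seed, so running the stages
## individually is bit-identical to run_pipeline() on the same config/seed.

.stage_seed <- function(seed, k) (seed * 7L + k * 1009L) %% 2147483641L

#' Pipeline stages
#'
#' `stage_simulate()` draws the population and renders raw logger series
#' per track plus clean calibration twilights and the SST field.
#' `stage_geolocate()` detects twilights, calibrates the zenith, computes
#' threshold positions and refines each track by MCMC.
#' `stage_segment()` builds daily features, fits/decodes the HMM per
#' track and extracts migration phenology. `stage_similarity()` builds
#' the whole/stage/period comparison tables from the migration-period
#' medians. `stage_stats()` runs repeatability, seasonal variability,
#' range correlation and the GLM suite.
#'
#' @param config a [sim_config()].
#' @param seed integer pipeline seed.
#' @param mask a `land_mask`.
#' @return stage-specific lists; see [run_pipeline()].
#' @export
stage_simulate <- function(config = sim_config(), seed = 1,
                           mask = read_land_mask()) {
  pop <- simulate_population(config, seed = .stage_seed(seed, 1L), mask = mask)
  field <- synthetic_sst_field()
  set.seed(.stage_seed(seed, 2L))
  loggers <- lapply(pop$tracks, function(tr) {
    list(track_id = sprintf("%s_%d", tr$individual_id, tr$year),
         light = render_light(tr, config),
         immersion = render_immersion(tr, config),
         sst = render_sst(tr, field, config))
  })
  calib <- simulate_calibration(config)
  list(population = pop, loggers = loggers, field = field,
       calibration = calib, mask = mask, config = config)
}

## Population-scale MCMC schedule: a documented scale-down of the full
## single-track schedule (which is refine_track_mcmc()'s default) so that a
## multi-deployment pipeline run stays within an interactive time budget on
## one CPU; see the methods vignette.
.pipeline_mcmc_defaults <- list(burn = 1000, conv_len = 300, conv_reps = 3,
                                n_chains = 2, chain_len = 1000, thin = 2,
                                max_restarts = 1, strict = FALSE)

#' @rdname stage_simulate
#' @param sim output of [stage_simulate()].
#' @param mcmc control overrides for [refine_track_mcmc()], merged over the
#'   pipeline's reduced population-scale schedule
#'   (`gadfly:::.pipeline_mcmc_defaults`).
#' @export
stage_geolocate <- function(sim, seed = 1, mcmc = list()) {
  cfg <- sim$config
  cal <- calibrate_zenith(sim$calibration, cfg$colony)
  if (cfg$twilight_noise) {
    cal$meanlog <- cfg$twilight_meanlog
    cal$sdlog <- cfg$twilight_sdlog
  }
  mcmc <- utils::modifyList(.pipeline_mcmc_defaults, mcmc)
  tracks <- list(); twl_all <- list()
  for (i in seq_along(sim$loggers)) {
    lg <- sim$loggers[[i]]
    twl <- detect_twilights(lg$light)
    init <- threshold_positions(twl, cal$zenith)
    post <- refine_track_mcmc(init, twl, cal,
                              mask = sim$mask, field = sim$field, sst = lg$sst,
                              control = mcmc,
                              seed = .stage_seed(seed, 100L + i))
    med <- summarize_posterior(post)
    med$track_id <- lg$track_id
    tracks[[i]] <- med
    twl$track_id <- lg$track_id
    twl_all[[i]] <- twl
  }
  list(calibration = cal, tracks = tracks, twilights = twl_all)
}

#' @rdname stage_simulate
#' @param geo output of [stage_geolocate()].
#' @param min_days minimum migration length in days.
#' @export
stage_segment <- function(sim, geo, seed = 1, min_days = 90) {
  phen <- list()
  for (i in seq_along(sim$loggers)) {
    lg <- sim$loggers[[i]]
    mig <- try({
      feats <- daily_features(lg$light, lg$immersion, geo$tracks[[i]],
                              sim$config$colony, geo$twilights[[i]],
                              tag_model = sim$config$tag_model)
      model <- fit_hmm(feats, seed = .stage_seed(seed, 200L + i))
      st <- decode_states(model, feats)
      extract_migrations(st, min_days = min_days)
    }, silent = TRUE)
    if (inherits(mig, "try-error")) {
      warning(sprintf("stage_segment: %s skipped (%s)", lg$track_id,
                      attr(mig, "condition")$message))
      next
    }
    mig <- mig[!mig$partial, , drop = FALSE]
    if (nrow(mig) == 0) next
    mig <- mig[which.max(mig$duration), , drop = FALSE]  # principal bout
    tr <- sim$population$truth[sim$population$truth$track_id == lg$track_id, ]
    phen[[length(phen) + 1L]] <- cbind(
      data.frame(track_id = lg$track_id, individual = tr$individual,
                 year = tr$year), mig)
  }
  do.call(rbind, phen)
}

#' @rdname stage_simulate
#' @param tracks list of summarised track data.frames with `track_id`.
#' @param phenology phenology table from [stage_segment()].
#' @param h,cell_km kernel SD and UD grid cell, km.
#' @export
stage_similarity <- function(tracks, phenology, h = 200, cell_km = 50) {
  all_tr <- do.call(rbind, tracks)
  locs <- list()
  for (r in seq_len(nrow(phenology))) {
    tid <- phenology$track_id[r]
    tt <- all_tr[all_tr$track_id == tid, ]
    sel <- tt$date >= phenology$departure_date[r] & tt$date < phenology$arrival_date[r]
    locs[[r]] <- data.frame(track_id = tid, date = tt$date[sel],
                            lon = tt$lon[sel], lat = tt$lat[sel])
  }
  locations <- do.call(rbind, locs)
  list(whole = pairwise_comparisons(locations, phenology, "whole",
                                    h = h, cell_km = cell_km),
       stages = pairwise_comparisons(locations, phenology, "stages"),
       periods = pairwise_comparisons(locations, phenology, "periods"),
       locations = locations)
}

#' @rdname stage_simulate
#' @param comparisons output of [stage_similarity()].
#' @param n_boot bootstrap iterations for repeatability.
#' @export
stage_stats <- function(phenology, comparisons, n_boot = 1000, seed = 1) {
  by_ind <- split(phenology, phenology$individual)
  rep_in <- function(col) {
    vals <- c(); ids <- c()
    for (ind in names(by_ind)) {
      d <- by_ind[[ind]]
      if (nrow(d) < 2) next
      v <- if (col == "duration") d$duration else to_signed_days(d[[col]])
      vals <- c(vals, v); ids <- c(ids, rep(ind, length(v)))
    }
    list(values = vals, ids = ids)
  }
  reps <- list()
  for (nm in c("departure_date", "arrival_date", "duration")) {
    x <- rep_in(nm)
    reps[[sub("_date", "", nm)]] <-
      if (length(unique(x$ids)) >= 2) {
        repeatability(x$values, x$ids, n_boot = n_boot,
                      seed = .stage_seed(seed, 300L))
      } else NULL
  }
  seas <- seasonal_variability(phenology)
  rngs <- merge(
    stats::aggregate(departure_date ~ individual, phenology,
                     function(d) diff(range(to_signed_days(d)))),
    stats::aggregate(arrival_date ~ individual, phenology,
                     function(d) diff(range(to_signed_days(d)))),
    by = "individual")
  multi <- phenology$individual[duplicated(phenology$individual)]
  rngs <- rngs[rngs$individual %in% multi, ]
  rng_cor <- if (nrow(rngs) >= 3) {
    pearson_range_correlation(rngs$departure_date, rngs$arrival_date)
  } else NULL
  # GLM suite on the comparison tables
  emd_glm <- ba_glm <- stage_glm <- period_glm <- NULL
  try_null <- function(expr) {
    out <- try(expr, silent = TRUE)
    if (inherits(out, "try-error")) NULL else out
  }
  w <- comparisons$whole
  if (!is.null(w) && nrow(w) > 5) {
    emd_glm <- stepwise_backward(fit_glm(
      w, emd_km ~ same_individual * dep_diff_days, "gamma", "identity"))
    if (all(is.finite(w$ba))) {
      wb <- w
      wb$ba <- pmin(pmax(wb$ba, 1e-6), 1 - 1e-6)
      ba_glm <- try(stepwise_backward(fit_glm(
        wb, ba ~ same_individual * dep_diff_days, "binomial", "log")), silent = TRUE)
      if (inherits(ba_glm, "try-error")) ba_glm <- NULL
    }
  }
  seg_glm <- function(seg_tab) {
    if (is.null(seg_tab) || nrow(seg_tab) < 10) return(NULL)
    wi <- w[w$same_individual == 1,
            c("id1", "id2", "dep_diff_days", "label", "emd_km")]
    tab <- rbind(wi, seg_tab[, c("id1", "id2", "dep_diff_days", "label", "emd_km")])
    tab$label <- stats::relevel(factor(tab$label), ref = "whole")
    stepwise_backward(fit_glm(tab, emd_km ~ label * dep_diff_days,
                              "gamma", "identity"))
  }
  stage_glm <- try_null(seg_glm(comparisons$stages))
  period_glm <- try_null(seg_glm(comparisons$periods))
  list(repeatability = reps, seasonal = seas, range_correlation = rng_cor,
       emd_glm = emd_glm, ba_glm = ba_glm,
       stage_glm = stage_glm, period_glm = period_glm)
}

#' Run the whole pipeline on a synthetic population
#'
#' Equivalent to calling the five stages in order with seeds derived from
#' `seed`; returns all intermediate products plus the statistical results.
#'
#' @param config a [sim_config()].
#' @param seed integer seed driving every stage.
#' @param mcmc control overrides for [refine_track_mcmc()].
#' @param n_boot bootstrap iterations in the stats stage.
#' @param mask a `land_mask`.
#' @return list with `sim`, `geo`, `phenology`, `comparisons`, `stats`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, mcmc = list(),
                         n_boot = 1000, mask = read_land_mask()) {
  sim <- stage_simulate(config, seed, mask)
  geo <- stage_geolocate(sim, seed, mcmc)
  phen <- stage_segment(sim, geo, seed)
  comp <- stage_similarity(geo$tracks, phen)
  st <- stage_stats(phen, comp, n_boot = n_boot, seed = seed)
  list(sim = sim, geo = geo, phenology = phen, comparisons = comp, stats = st)
}
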