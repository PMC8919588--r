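# A compact 30-day out-and-residency trajectory with shading-delayed
# twilights, logger SST and ground truth, reused by the geolocation and
# acceptance tests.
make_refinement_scenario <- function(seed = 42, n = 30, meanlog = 2.2, sdlog = 1.0,
                                     zenith = 96, sst_noise = 0.3) {
  set.seed(seed)
  lons <- c(seq(57.78, 80, length.out = 12), 80 + rnorm(n - 12, 0, 1))
  lats <- c(seq(-19.85, -12, length.out = 12), -12 + rnorm(n - 12, 0, 1))
  dates <- seq(as.Date("2016-08-01"), by = "day", length.out = n)
  rise <- solar_twilight_time(lons, lats, dates, zenith, "rise")
  set_ <- solar_twilight_time(lons, lats, dates, zenith, "set")
  rise_o <- rise + 60 * rlnorm(n, meanlog, sdlog)
  set_o <- set_ - 60 * rlnorm(n, meanlog, sdlog)
  tw <- rbind(data.frame(time = rise_o, kind = "rise"),
              data.frame(time = set_o, kind = "set"))
  tw <- tw[order(tw$time), ]
  field <- synthetic_sst_field()
  sstv <- sst_at(field, lons, lats, dates) + rnorm(n, 0, sst_noise)
  sst <- sst_log(as.POSIXct(paste(dates, "06:00:00"), tz = "UTC"), sstv)
  list(twilights = tw, truth_lon = rep(lons, each = 2),
       truth_lat = rep(lats, each = 2), dates = dates,
       field = field, sst = sst, zenith = zenith,
       calibration = list(zenith = zenith, meanlog = meanlog, sdlog = sdlog))
}

# reduced MCMC schedule for module-level property tests (the acceptance
# suite runs the full stated schedule once)
fast_mcmc <- list(burn = 500, conv_len = 150, chain_len = 500, n_chains = 2,
                  thin = 2, strict = FALSE)
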