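## Solar ephemeris (NOAA low-precision algorithm): declination, equation of
## time, zenith angle and threshold-crossing (twilight) times. Accuracy is
## well under 0.01 deg zenith / a few seconds of event time, far below
## geolocator noise.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Solar declination and equation of time
#'
#' @param time `POSIXct` (UTC).
#' @return list with `declination` (degrees) and `eqtime` (minutes; add to
#'   mean solar time to get apparent solar time).
#' @export
solar_position <- function(time) {
  jd <- as.numeric(as.POSIXct(time, tz = "UTC")) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  l0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  mr <- .deg2rad(m)
  c <- sin(mr) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * mr) * (0.019993 - 0.000101 * jc) +
    sin(3 * mr) * 0.000289
  true_long <- l0 + c
  omega <- .deg2rad(125.04 - 1934.136 * jc)
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  e0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  ec <- e0 + 0.00256 * cos(omega)
  decl <- .rad2deg(asin(sin(.deg2rad(ec)) * sin(.deg2rad(app_long))))
  y <- tan(.deg2rad(ec) / 2)^2
  l0r <- .deg2rad(l0)
  eqtime <- 4 * .rad2deg(
    y * sin(2 * l0r) - 2 * e * sin(mr) + 4 * e * y * sin(mr) * cos(2 * l0r) -
      0.5 * y^2 * sin(4 * l0r) - 1.25 * e^2 * sin(2 * mr)
  )
  list(declination = decl, eqtime = eqtime)
}

#' Solar zenith angle at a time and place
#'
#' @param lon,lat degrees (longitude east-positive).
#' @param time `POSIXct` (UTC).
#' @return zenith angle in degrees (0 = sun overhead, 90 = horizon).
#' @export
solar_zenith <- function(lon, lat, time) {
  sp <- solar_position(time)
  t <- as.POSIXct(time, tz = "UTC")
  mins <- (as.numeric(t) / 60) %% 1440
  tst <- (mins + sp$eqtime + 4 * lon) %% 1440
  ha <- .deg2rad(tst / 4 - 180)
  phi <- .deg2rad(lat)
  dec <- .deg2rad(sp$declination)
  cz <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(ha)
  .rad2deg(acos(pmin(1, pmax(-1, cz))))
}

#' Time the sun crosses a given zenith angle (twilight time)
#'
#' Solves the hour-angle equation for the moment the sun's zenith angle
#' equals `zenith` on `date` at (`lon`, `lat`), refining the solar
#' declination/equation-of-time at the event time iteratively.
#'
#' @param lon,lat degrees; `|lat| <= 89`.
#' @param date `Date` (the UTC civil date near which the event falls).
#' @param zenith zenith angle in degrees defining the light threshold
#'   (e.g. 96 for typical geolocator thresholds).
#' @param kind `"rise"` (morning, upward light crossing) or `"set"`.
#' @return `POSIXct` UTC, `NA` where the sun never crosses that zenith on
#'   that date (polar day/night for that threshold).
#' @export
solar_twilight_time <- function(lon, lat, date, zenith, kind = c("rise", "set")) {
  kind <- match.arg(kind, several.ok = TRUE)
  n <- max(length(lon), length(lat), length(date), length(zenith), length(kind))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  date <- rep_len(as.Date(date), n); zenith <- rep_len(zenith, n)
  kind <- rep_len(kind, n)
  stopifnot(all(abs(lat) <= 89))
  sgn <- ifelse(kind == "rise", -1, 1)
  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  # start at local solar noon, iterate to convergence
  t <- midnight + 60 * ((720 - 4 * lon) %% 1440)
  for (i in 1:3) {
    sp <- solar_position(t)
    phi <- .deg2rad(lat); dec <- .deg2rad(sp$declination)
    cosha <- (cos(.deg2rad(zenith)) - sin(phi) * sin(dec)) / (cos(phi) * cos(dec))
    ha <- .rad2deg(acos(pmin(1, pmax(-1, cosha))))
    mins <- 720 - 4 * lon - sp$eqtime + sgn * 4 * ha
    t <- midnight + 60 * mins
    bad <- abs(cosha) > 1
  }
  t[bad] <- NA
  t
}
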