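## Logger-file schema, validated series containers, deployment metadata and
## gridded SST field I/O. All files are plain delimited text / JSON so that
## pipelines are reproducible without proprietary tag formats.

#' Tag-model constants
#'
#' Two logger classes are supported: `"low-range"` tags record only low
#' light levels (light threshold 4 for twilights, interference below 64,
#' immersion conductivity tested every 3 s so 10-min wet counts run 0-200)
#' and `"full-range"` tags record the whole light range (threshold 1,
#' interference below 100, immersion tested every 30 s, wet counts 0-20).
#'
#' @param tag_model `"low-range"` or `"full-range"`.
#' @return list with `light_threshold`, `interference_threshold`,
#'   `wet_max`, `light_day` (typical unshaded daytime reading).
#' @export
tag_params <- function(tag_model = c("full-range", "low-range")) {
  tag_model <- match.arg(tag_model)
  if (tag_model == "low-range") {
    list(tag_model = tag_model, light_threshold = 4, interference_threshold = 64,
         wet_max = 200L, light_day = 64)
  } else {
    list(tag_model = tag_model, light_threshold = 1, interference_threshold = 100,
         wet_max = 20L, light_day = 200)
  }
}

.check_timestamps <- function(ts, what) {
  if (anyNA(ts)) {
    stop(sprintf("%s: unparseable timestamp at row %d", what, which(is.na(ts))[1]))
  }
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    i <- which(d <= 0)[1] + 1L
    stop(sprintf("%s: timestamps not strictly increasing at row %d (%s)",
                 what, i, format(ts[i], "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  }
  gaps <- which(d > 600 + 1)
  if (length(gaps)) {
    data.frame(after = ts[gaps], gap_minutes = d[gaps] / 60)
  } else {
    data.frame(after = ts[0], gap_minutes = numeric(0))
  }
}

#' Validated logger series containers
#'
#' Constructors for the three raw series a geolocator produces: maximum
#' light per 10-min interval, wet (saltwater immersion) counts per 10-min
#' interval, and logger SST readings. Timestamps must be strictly
#' increasing UTC; gaps relative to the 10-min cadence are tolerated and
#' recorded in the `"gaps"` attribute, never interpolated.
#'
#' @param timestamps `POSIXct` (UTC).
#' @param light,wet_count,temp_c series values.
#' @param tag_model see [tag_params()].
#' @return a data.frame of class `light_series` / `immersion_series` /
#'   `sst_log` with attributes `tag_model` and `gaps`.
#' @export
light_series <- function(timestamps, light, tag_model = "full-range") {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  gaps <- .check_timestamps(timestamps, "light series")
  if (any(light < 0, na.rm = TRUE)) stop("light series: negative light value")
  structure(data.frame(timestamp = timestamps, light = as.numeric(light)),
            tag_model = tag_model, gaps = gaps,
            class = c("light_series", "data.frame"))
}

#' @rdname light_series
#' @export
immersion_series <- function(timestamps, wet_count, tag_model = "full-range") {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  gaps <- .check_timestamps(timestamps, "immersion series")
  wmax <- tag_params(tag_model)$wet_max
  bad <- which(wet_count < 0 | wet_count > wmax)
  if (length(bad)) {
    stop(sprintf("immersion series: wet_count %d outside 0..%d for %s tag at row %d",
                 wet_count[bad[1]], wmax, tag_model, bad[1]))
  }
  structure(data.frame(timestamp = timestamps, wet_count = as.integer(wet_count)),
            tag_model = tag_model, gaps = gaps,
            class = c("immersion_series", "data.frame"))
}

#' @rdname light_series
#' @export
sst_log <- function(timestamps, temp_c) {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  gaps <- .check_timestamps(timestamps, "SST log")
  if (any(temp_c < -2 | temp_c > 40, na.rm = TRUE)) {
    stop("SST log: temperature outside -2..40 C")
  }
  structure(data.frame(timestamp = timestamps, temp_c = as.numeric(temp_c)),
            gaps = gaps, class = c("sst_log", "data.frame"))
}

.read_two_col <- function(path, value_name) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("%s: expected columns timestamp,%s", path, value_name))
  ts <- as.POSIXct(df[[1]], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  list(timestamps = ts, value = df[[2]])
}

#' Read a deployment's raw logger files
#'
#' @param paths named list/vector with elements `light`, `immersion`,
#'   `sst` (any may be omitted); each a CSV `timestamp,value` with
#'   ISO-8601 UTC timestamps at (nominally) 10-min spacing.
#' @param tag_model see [tag_params()].
#' @return list with `light`, `immersion`, `sst` (validated series or
#'   `NULL`).
#' @export
read_logger_files <- function(paths, tag_model = "full-range") {
  out <- list(light = NULL, immersion = NULL, sst = NULL)
  if (!is.null(paths[["light"]])) {
    x <- .read_two_col(paths[["light"]], "light")
    out$light <- light_series(x$timestamps, x$value, tag_model)
  }
  if (!is.null(paths[["immersion"]])) {
    x <- .read_two_col(paths[["immersion"]], "wet_count")
    out$immersion <- immersion_series(x$timestamps, x$value, tag_model)
  }
  if (!is.null(paths[["sst"]])) {
    x <- .read_two_col(paths[["sst"]], "temp_c")
    out$sst <- sst_log(x$timestamps, x$value)
  }
  out
}

#' Write logger series back to the on-disk schema
#'
#' @param series a `light_series`, `immersion_series` or `sst_log`.
#' @param path output CSV path.
#' @export
write_logger_file <- function(series, path) {
  df <- data.frame(timestamp = format(series[[1]], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   value = series[[2]])
  names(df)[2] <- names(series)[2]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Deployment metadata
#'
#' @param individual_id,tag_id identifiers.
#' @param colony `c(lon, lat)` degrees.
#' @param calibration_start,calibration_end calibration window at a known
#'   location (3-5 days).
#' @param deploy_date,retrieve_date deployment interval.
#' @param tag_model see [tag_params()].
#' @return list of class `deployment`.
#' @export
deployment <- function(individual_id, tag_id, colony,
                       calibration_start, calibration_end,
                       deploy_date, retrieve_date, tag_model = "full-range") {
  calibration_start <- as.Date(calibration_start)
  calibration_end <- as.Date(calibration_end)
  ndays <- as.integer(calibration_end - calibration_start)
  if (ndays < 3 || ndays > 5) {
    stop("deployment: calibration window must span 3-5 days")
  }
  if (abs(colony[2]) > 90 || colony[1] < -180 || colony[1] >= 360) {
    stop("deployment: colony coordinates invalid")
  }
  structure(list(individual_id = individual_id, tag_id = tag_id,
                 colony = as.numeric(colony),
                 calibration_start = calibration_start,
                 calibration_end = calibration_end,
                 deploy_date = as.Date(deploy_date),
                 retrieve_date = as.Date(retrieve_date),
                 tag_model = tag_model),
            class = "deployment")
}

#' @rdname deployment
#' @param path JSON file of deployment fields.
#' @export
read_deployment <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  deployment(x$individual_id, x$tag_id, unlist(x$colony),
             x$calibration_start, x$calibration_end,
             x$deploy_date, x$retrieve_date,
             if (is.null(x$tag_model)) "full-range" else x$tag_model)
}

#' Gridded weekly SST field container and I/O
#'
#' Weekly mean sea-surface temperatures on a regular 1.0 x 1.0 degree grid
#' (the structure of remotely sensed optimum-interpolation SST products).
#' On disk: CSV with columns `lon, lat, week, temp_c`.
#'
#' @param lons,lats,weeks grid coordinate vectors (degrees; week 1..53).
#' @param temp numeric array `[lon, lat, week]` in degrees C.
#' @return list of class `sst_field`.
#' @export
sst_field <- function(lons, lats, weeks, temp) {
  stopifnot(length(dim(temp)) == 3,
            dim(temp)[1] == length(lons),
            dim(temp)[2] == length(lats),
            dim(temp)[3] == length(weeks))
  structure(list(lons = lons, lats = lats, weeks = as.integer(weeks), temp = temp),
            class = "sst_field")
}

#' @rdname sst_field
#' @param path CSV path.
#' @export
read_sst_field <- function(path) {
  df <- utils::read.csv(path)
  lons <- sort(unique(df$lon)); lats <- sort(unique(df$lat))
  weeks <- sort(unique(df$week))
  a <- array(NA_real_, c(length(lons), length(lats), length(weeks)))
  a[cbind(match(df$lon, lons), match(df$lat, lats), match(df$week, weeks))] <- df$temp_c
  sst_field(lons, lats, weeks, a)
}

#' @rdname sst_field
#' @param field an `sst_field`.
#' @export
write_sst_field <- function(field, path) {
  g <- expand.grid(lon = field$lons, lat = field$lats, week = field$weeks)
  g$temp_c <- as.vector(field$temp)
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
}

#' Interpolate an SST field at points
#'
#' Bilinear in space, nearest in week; coordinates outside the grid are
#' clamped to the edge.
#'
#' @param field an `sst_field`.
#' @param lon,lat degrees; `date` a `Date` (mapped to week of year).
#' @return temperatures, degrees C.
#' @export
sst_at <- function(field, lon, lat, date) {
  week <- pmin(as.integer(format(as.Date(date), "%U")) + 1L, max(field$weeks))
  wk <- pmax(match(pmin(pmax(week, min(field$weeks)), max(field$weeks)), field$weeks), 1L)
  nx <- length(field$lons); ny <- length(field$lats)
  fx <- (lon - field$lons[1]) / (field$lons[2] - field$lons[1])
  fy <- (lat - field$lats[1]) / (field$lats[2] - field$lats[1])
  fx <- pmin(pmax(fx, 0), nx - 1 - 1e-9)
  fy <- pmin(pmax(fy, 0), ny - 1 - 1e-9)
  i <- floor(fx); j <- floor(fy)
  tx <- fx - i; ty <- fy - j
  idx <- function(ii, jj) cbind(ii + 1, jj + 1, wk)
  (1 - tx) * (1 - ty) * field$temp[idx(i, j)] +
    tx * (1 - ty) * field$temp[idx(i + 1, j)] +
    (1 - tx) * ty * field$temp[idx(i, j + 1)] +
    tx * ty * field$temp[idx(i + 1, j + 1)]
}

#' Write / read a position track table
#'
#' Column layout: `individual, year, epoch, date, lon_med, lat_med,
#' lon_lo, lon_hi, lat_lo, lat_hi`.
#'
#' @param track a track data.frame (see [summarize_posterior()]).
#' @param path CSV path.
#' @export
write_track <- function(track, path) {
  df <- track
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
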