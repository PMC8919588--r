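## Spherical / ellipsoidal geometry helpers shared across modules.

.EARTH_RADIUS_KM <- 6371

#' Great-circle (Haversine) distance in kilometres
#'
#' Sphere radius 6371 km; this is the ground distance used by the earth
#' mover's distance between migration point sets.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorised).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1); dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * .EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Geodesic distance on the WGS84 ellipsoid (Vincenty inverse), metres
#'
#' Used for the daily colony-distance feature. Falls back to spherical
#' distance in the (astronomically unlikely) event of non-convergence for
#' near-antipodal points.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorised).
#' @return distance(s) in metres.
#' @export
geodesic_m <- function(lon1, lat1, lon2, lat2) {
  a <- 6378137; f <- 1 / 298.257223563; b <- a * (1 - f)
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  lon1 <- rep_len(lon1, n); lat1 <- rep_len(lat1, n)
  lon2 <- rep_len(lon2, n); lat2 <- rep_len(lat2, n)
  u1 <- atan((1 - f) * tan(.deg2rad(lat1)))
  u2 <- atan((1 - f) * tan(.deg2rad(lat2)))
  ll <- .deg2rad(lon2 - lon1)
  lambda <- ll
  su1 <- sin(u1); cu1 <- cos(u1); su2 <- sin(u2); cu2 <- cos(u2)
  out <- numeric(n)
  for (it in 1:200) {
    sl <- sin(lambda); cl <- cos(lambda)
    sin_sigma <- sqrt((cu2 * sl)^2 + (cu1 * su2 - su1 * cu2 * cl)^2)
    cos_sigma <- su1 * su2 + cu1 * cu2 * cl
    sigma <- atan2(sin_sigma, cos_sigma)
    sin_alpha <- ifelse(sin_sigma == 0, 0, cu1 * cu2 * sl / sin_sigma)
    cos2_alpha <- 1 - sin_alpha^2
    cos_2sm <- ifelse(cos2_alpha == 0, 0, cos_sigma - 2 * su1 * su2 / pmax(cos2_alpha, 1e-300))
    cc <- f / 16 * cos2_alpha * (4 + f * (4 - 3 * cos2_alpha))
    lambda_new <- ll + (1 - cc) * f * sin_alpha *
      (sigma + cc * sin_sigma * (cos_2sm + cc * cos_sigma * (-1 + 2 * cos_2sm^2)))
    done <- abs(lambda_new - lambda) < 1e-12
    lambda <- lambda_new
    if (all(done)) break
  }
  sl <- sin(lambda); cl <- cos(lambda)
  sin_sigma <- sqrt((cu2 * sl)^2 + (cu1 * su2 - su1 * cu2 * cl)^2)
  cos_sigma <- su1 * su2 + cu1 * cu2 * cl
  sigma <- atan2(sin_sigma, cos_sigma)
  sin_alpha <- ifelse(sin_sigma == 0, 0, cu1 * cu2 * sl / sin_sigma)
  cos2_alpha <- 1 - sin_alpha^2
  cos_2sm <- ifelse(cos2_alpha == 0, 0, cos_sigma - 2 * su1 * su2 / pmax(cos2_alpha, 1e-300))
  u2sq <- cos2_alpha * (a^2 - b^2) / b^2
  aa <- 1 + u2sq / 16384 * (4096 + u2sq * (-768 + u2sq * (320 - 175 * u2sq)))
  bb <- u2sq / 1024 * (256 + u2sq * (-128 + u2sq * (74 - 47 * u2sq)))
  dsigma <- bb * sin_sigma * (cos_2sm + bb / 4 * (cos_sigma * (-1 + 2 * cos_2sm^2) -
    bb / 6 * cos_2sm * (-3 + 4 * sin_sigma^2) * (-3 + 4 * cos_2sm^2)))
  d <- b * aa * (sigma - dsigma)
  same <- abs(lat1 - lat2) < 1e-12 & abs(lon1 - lon2) < 1e-12
  d[same] <- 0
  d
}

#' Lambert azimuthal equal-area projection (forward), kilometres
#'
#' Spherical form, used to build the planar grids on which kernel
#' utilisation distributions are estimated.
#'
#' @param lon,lat points in degrees.
#' @param center length-2 `c(lon0, lat0)` projection centre in degrees.
#' @return data.frame with planar `x`, `y` in km.
#' @export
laea_project <- function(lon, lat, center) {
  lam0 <- .deg2rad(center[1]); phi0 <- .deg2rad(center[2])
  lam <- .deg2rad(lon); phi <- .deg2rad(lat)
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / pmax(denom, 1e-12))
  data.frame(
    x = .EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0),
    y = .EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  )
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param lon,lat query points in degrees.
#' @param polygons list of two-column matrices (lon, lat rings); a point is
#'   inside if it falls in an odd number of rings.
#' @return logical vector.
#' @export
point_in_polygons <- function(lon, lat, polygons) {
  inside <- rep(FALSE, length(lon))
  for (ring in polygons) {
    px <- ring[, 1]; py <- ring[, 2]
    np <- length(px)
    j <- c(np, seq_len(np - 1L))
    hit <- rep(FALSE, length(lon))
    for (k in seq_len(np)) {
      xi <- px[k]; yi <- py[k]; xj <- px[j[k]]; yj <- py[j[k]]
      cross <- ((yi > lat) != (yj > lat)) &
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      hit <- xor(hit, cross)
    }
    inside <- inside | hit
  }
  inside
}

#' Land mask
#'
#' Reads polygon rings from a GeoJSON file (`Polygon` / `MultiPolygon`
#' geometries; outer rings only). The package ships a deliberately coarse,
#' synthetic simplification of the Indian Ocean's surrounding land masses
#' as a default fixture.
#'
#' @param path GeoJSON file; default the shipped coarse mask.
#' @return object of class `land_mask`: list of ring matrices.
#' @export
read_land_mask <- function(path = system.file("extdata", "indian_ocean_landmask_synthetic.geojson",
                                              package = "gadfly")) {
  gj <- jsonlite::read_json(path)
  rings <- list()
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    ring_of <- function(r) {
      m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
      storage.mode(m) <- "double"
      m
    }
    if (geom$type == "Polygon") {
      rings <- c(rings, list(ring_of(geom$coordinates[[1]])))
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) rings <- c(rings, list(ring_of(poly[[1]])))
    }
  }
  structure(rings, class = "land_mask")
}

#' Is a point on land?
#'
#' @param lon,lat degrees.
#' @param mask a `land_mask` (see [read_land_mask()]).
#' @return logical vector.
#' @export
on_land <- function(lon, lat, mask) point_in_polygons(lon, lat, mask)
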