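## Spatial and spatiotemporal similarity of migrations: exact earth mover's
## distance with Haversine ground cost, kernel utilisation distributions on
## an equal-area grid with Bhattacharyya's affinity, and the 30-day-period /
## six-stage decompositions of each migration.

#' Earth mover's distance between two location sets, in kilometres
#'
#' Optimal-transport cost between two weighted point sets on the sphere
#' with great-circle (Haversine) ground distance, solved exactly as a
#' transportation problem. Unlike overlap indices, non-overlapping
#' distributions still receive a graded dissimilarity: the value is the
#' minimal total effort (weight x km) of morphing one distribution into
#' the other, zero for identical sets.
#'
#' @param a,b data.frames with columns `lon`, `lat` and optionally
#'   `weight` (defaults to uniform; weights are normalised to sum 1).
#' @return distance in km (weight-averaged transport cost).
#' @export
emd <- function(a, b) {
  pa <- .as_pointset(a); pb <- .as_pointset(b)
  .emd_points(pa$lon, pa$lat, pa$weight, pb$lon, pb$lat, pb$weight)
}

.as_pointset <- function(x) {
  if (!all(c("lon", "lat") %in% names(x))) stop("point set needs lon, lat columns")
  if (nrow(x) < 1) stop("point set is empty")
  w <- if ("weight" %in% names(x)) x$weight else rep(1, nrow(x))
  if (any(w < 0)) stop("negative point weight")
  # merge coincident points (exactness preserved; smaller solver instances)
  key <- paste(x$lon, x$lat)
  agg <- rowsum(w, key, reorder = FALSE)
  first <- !duplicated(key)
  data.frame(lon = x$lon[first], lat = x$lat[first],
             weight = as.numeric(agg) / sum(w))
}

#' Kernel utilisation distribution on an equal-area grid
#'
#' Points are projected with a Lambert azimuthal equal-area projection
#' (centred on the point centroid unless a shared grid is supplied) and
#' smoothed with an isotropic Gaussian kernel whose standard deviation `h`
#' absorbs geolocator precision error (default 200 km). The result is a
#' discrete probability surface (cell masses summing to 1).
#'
#' @param points data.frame with `lon`, `lat`.
#' @param h kernel SD in km.
#' @param cell_km grid cell size in km.
#' @param grid optional shared grid from [ud_grid()]; built from the
#'   points (+3h margin) when omitted.
#' @return object of class `ud`: list with `grid` and matrix `p`.
#' @export
make_ud <- function(points, h = 200, cell_km = 50, grid = NULL) {
  if (is.null(grid)) grid <- ud_grid(points, h = h, cell_km = cell_km)
  xy <- laea_project(points$lon, points$lat, grid$center)
  nx <- grid$nx; ny <- grid$ny
  p <- matrix(0, nx, ny)
  cx <- grid$x0 + (seq_len(nx) - 0.5) * grid$cell
  cy <- grid$y0 + (seq_len(ny) - 0.5) * grid$cell
  r <- ceiling(5 * h / grid$cell)  # truncation radius, mass loss < 1e-6
  for (k in seq_len(nrow(xy))) {
    i0 <- floor((xy$x[k] - grid$x0) / grid$cell) + 1
    j0 <- floor((xy$y[k] - grid$y0) / grid$cell) + 1
    ii <- max(1, i0 - r):min(nx, i0 + r)
    jj <- max(1, j0 - r):min(ny, j0 + r)
    if (!length(ii) || !length(jj)) next
    gx <- stats::dnorm(cx[ii], xy$x[k], h)
    gy <- stats::dnorm(cy[jj], xy$y[k], h)
    p[ii, jj] <- p[ii, jj] + outer(gx, gy)
  }
  s <- sum(p)
  if (s <= 0) stop("make_ud: all kernel mass fell outside the grid")
  structure(list(grid = grid, p = p / s), class = "ud")
}

#' @rdname make_ud
#' @param center optional `c(lon, lat)` projection centre (defaults to the
#'   centroid of all supplied positions).
#' @export
ud_grid <- function(points, h = 200, cell_km = 50, center = NULL) {
  if (is.null(center)) center <- c(mean(points$lon), mean(points$lat))
  xy <- laea_project(points$lon, points$lat, center)
  m <- 3 * h
  x0 <- floor((min(xy$x) - m) / cell_km) * cell_km
  y0 <- floor((min(xy$y) - m) / cell_km) * cell_km
  nx <- ceiling((max(xy$x) + m - x0) / cell_km)
  ny <- ceiling((max(xy$y) + m - y0) / cell_km)
  list(center = center, x0 = x0, y0 = y0, nx = nx, ny = ny, cell = cell_km)
}

#' Bhattacharyya's affinity between two utilisation distributions
#'
#' \eqn{BA = \sum_{cells} \sqrt{p q}}: 0 for disjoint distributions, 1 for
#' identical ones. Both UDs must live on the same grid.
#'
#' @param ud1,ud2 `ud` objects from [make_ud()].
#' @return affinity in \[0, 1\].
#' @export
bhattacharyya <- function(ud1, ud2) {
  g1 <- ud1$grid; g2 <- ud2$grid
  same <- isTRUE(all.equal(g1[c("center", "x0", "y0", "nx", "ny", "cell")],
                           g2[c("center", "x0", "y0", "nx", "ny", "cell")]))
  if (!same) stop("bhattacharyya: UDs are on different grids")
  min(1, sum(sqrt(ud1$p * ud2$p)))
}

#' Split a migration's locations into 30-day periods or six equal stages
#'
#' Periods are consecutive 30-day blocks counted from departure,
#' irrespective of migration start date; a trailing remainder shorter than
#' 30 days is dropped. Stages divide the whole bout into six contiguous
#' blocks of near-equal length (`floor(d/6)` or `ceiling(d/6)` days, the
#' longer blocks first) that jointly span the entire migration.
#'
#' @param locations data.frame with `date`, `lon`, `lat` for one
#'   migration.
#' @param departure,arrival `Date` bounds of the bout (departure = first
#'   at-sea day, arrival = first ashore day after).
#' @param period_days period length (default 30).
#' @return named list of point-set data.frames (`p1`, `p2`, ... or
#'   `s1`..`s6`).
#' @export
split_periods <- function(locations, departure, arrival, period_days = 30) {
  d <- as.integer(as.Date(arrival) - as.Date(departure))
  if (d < period_days) stop("split_periods: bout shorter than one period")
  nb <- d %/% period_days
  off <- as.integer(as.Date(locations$date) - as.Date(departure))
  keep <- off >= 0 & off < nb * period_days
  blk <- off[keep] %/% period_days + 1L
  out <- split(locations[keep, c("lon", "lat", "date")], blk)
  names(out) <- paste0("p", seq_along(out))
  out
}

#' @rdname split_periods
#' @param n_stages number of equal stages (default 6).
#' @export
split_stages <- function(locations, departure, arrival, n_stages = 6) {
  d <- as.integer(as.Date(arrival) - as.Date(departure))
  if (d < n_stages) stop("split_stages: bout shorter than the number of stages")
  base <- d %/% n_stages; extra <- d %% n_stages
  lens <- c(rep(base + 1L, extra), rep(base, n_stages - extra))
  ends <- cumsum(lens); starts <- c(0L, ends[-n_stages])
  off <- as.integer(as.Date(locations$date) - as.Date(departure))
  out <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    out[[s]] <- locations[off >= starts[s] & off < ends[s], c("lon", "lat", "date")]
  }
  names(out) <- paste0("s", seq_len(n_stages))
  out
}

#' Pairwise similarity tables between migration tracks
#'
#' In `"whole"` mode every unordered pair of tracks is compared with EMD
#' and BA; rows carry a same-individual flag and the (circular) absolute
#' difference in departure day between the two tracks. In `"stages"` /
#' `"periods"` mode only within-individual pairs are compared, matched by
#' stage/period index (periods truncated to the shorter migration's
#' count), and rows are labelled `s1..s6` / `p1..pK`.
#'
#' @param locations data.frame `track_id, date, lon, lat` (migration-period
#'   positions, e.g. twice-daily posterior medians).
#' @param phenology data.frame `track_id, individual, departure_date,
#'   arrival_date` (one row per track).
#' @param mode `"whole"`, `"stages"` or `"periods"`.
#' @param h,cell_km kernel SD and grid cell (km) for the BA surface.
#' @param compute_ba also compute BA (default: whole mode only).
#' @param period_days,n_stages see [split_periods()] / [split_stages()].
#' @return a comparison table data.frame: `id1, id2, same_individual,
#'   dep_diff_days, label, emd_km, ba`.
#' @export
pairwise_comparisons <- function(locations, phenology,
                                 mode = c("whole", "stages", "periods"),
                                 h = 200, cell_km = 50,
                                 compute_ba = (mode[1] == "whole"),
                                 period_days = 30, n_stages = 6) {
  mode <- match.arg(mode)
  ids <- phenology$track_id
  locs <- split(locations[, c("lon", "lat", "date")], locations$track_id)[as.character(ids)]
  depday <- day_index(phenology$departure_date)
  rows <- list()
  if (mode == "whole") {
    uds <- NULL
    if (compute_ba) {
      grid <- ud_grid(locations, h = h, cell_km = cell_km)
      uds <- lapply(locs, make_ud, h = h, cell_km = cell_km, grid = grid)
    }
    n <- length(ids)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j],
          same_individual = as.integer(phenology$individual[i] == phenology$individual[j]),
          dep_diff_days = day_diff_circular(depday[i], depday[j]),
          label = "whole",
          emd_km = emd(locs[[i]], locs[[j]]),
          ba = if (compute_ba) bhattacharyya(uds[[i]], uds[[j]]) else NA_real_)
      }
    }
  } else {
    splitter <- if (mode == "stages") {
      function(k) split_stages(locs[[k]], phenology$departure_date[k],
                               phenology$arrival_date[k], n_stages)
    } else {
      function(k) split_periods(locs[[k]], phenology$departure_date[k],
                                phenology$arrival_date[k], period_days)
    }
    pieces <- lapply(seq_along(ids), splitter)
    for (ind in unique(phenology$individual)) {
      ks <- which(phenology$individual == ind)
      if (length(ks) < 2) next
      for (ai in seq_along(ks)[-length(ks)]) {
        for (bi in (ai + 1):length(ks)) {
          i <- ks[ai]; j <- ks[bi]
          nseg <- min(length(pieces[[i]]), length(pieces[[j]]))
          for (s in seq_len(nseg)) {
            pi_ <- pieces[[i]][[s]]; pj_ <- pieces[[j]][[s]]
            if (nrow(pi_) == 0 || nrow(pj_) == 0) next
            ba <- NA_real_
            if (compute_ba) {
              grid <- ud_grid(rbind(pi_[c("lon", "lat")], pj_[c("lon", "lat")]),
                              h = h, cell_km = cell_km)
              ba <- bhattacharyya(make_ud(pi_, h, cell_km, grid),
                                  make_ud(pj_, h, cell_km, grid))
            }
            rows[[length(rows) + 1L]] <- data.frame(
              id1 = ids[i], id2 = ids[j], same_individual = 1L,
              dep_diff_days = day_diff_circular(depday[i], depday[j]),
              label = names(pieces[[i]])[s],
              emd_km = emd(pi_, pj_), ba = ba)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id1 = character(), id2 = character(),
                      same_individual = integer(), dep_diff_days = numeric(),
                      label = character(), emd_km = numeric(), ba = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
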