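#' Kernel utilization distribution of dive locations
#'
#' Fixed-bandwidth bivariate kernel density estimate on a regular grid in an
#' azimuthal-equidistant projection centred on the colony, so the bandwidth
#' and cell size are true kilometres. The kernel is an isotropic bivariate
#' Gaussian with sd = `h_km` in each axis; the grid extends at least
#' `4 * h_km` beyond the point cloud and the cell masses are normalised to
#' total 1 over the grid.
#'
#' @param points Dive (or fix) locations: data frame / matrix with `lon`,
#'   `lat` columns, all within 1000 km of the colony.
#' @param colony Colony `c(lon, lat)`.
#' @param h_km Smoothing bandwidth in km (default 10).
#' @param cell_km Grid cell size in km (default 1).
#' @return Object of class `cpf_ud`: list with `x`, `y` (cell-centre
#'   coordinates in km east/north of the colony), `mass` (matrix
#'   `length(x)` x `length(y)` of cell probability masses summing to 1),
#'   `h_km`, `cell_km`, `colony`, `n_points`.
#' @export
kde_ud <- function(points, colony, h_km = 10, cell_km = 1) {
  pts <- as_lonlat(points)
  if (nrow(pts) == 0L) stop("need at least one point")
  xy <- project_aeq(pts, colony)
  if (any(sqrt(xy[, 1]^2 + xy[, 2]^2) > 1000))
    stop("points must lie within 1000 km of the colony")
  if (h_km <= 0 || cell_km <= 0) stop("h_km and cell_km must be positive")
  pad <- 4 * h_km
  gx <- seq(floor(min(xy[, 1]) - pad), ceiling(max(xy[, 1]) + pad), by = cell_km)
  gy <- seq(floor(min(xy[, 2]) - pad), ceiling(max(xy[, 2]) + pad), by = cell_km)
  kx <- outer(gx, xy[, 1], function(g, p) stats::dnorm(g, p, h_km))
  ky <- outer(gy, xy[, 2], function(g, p) stats::dnorm(g, p, h_km))
  dens <- kx %*% t(ky)           # sum over points of separable Gaussians
  mass <- dens / sum(dens)
  structure(list(x = gx, y = gy, mass = mass, h_km = h_km,
                 cell_km = cell_km, colony = as_lonlat(colony),
                 n_points = nrow(xy)),
            class = "cpf_ud")
}

#' @export
print.cpf_ud <- function(x, ...) {
  cat("cpf_ud:", length(x$x), "x", length(x$y), "grid (",
      x$cell_km, "km cells ), h =", x$h_km, "km,", x$n_points, "points\n")
  invisible(x)
}

#' Utilization-distribution contour (cumulative-mass isopleth)
#'
#' The `level` isopleth is the smallest set of grid cells holding at least
#' `level` of the total probability mass: cells are accumulated in order of
#' decreasing density until the level is reached (the "volume" contour of
#' home-range analysis, not a density quantile). The boundary is also
#' polygonised at the density of the last included cell and returned in
#' lon/lat.
#'
#' @param ud A [kde_ud()] grid.
#' @param level Cumulative mass level in (0, 1); 0.5 gives the core area.
#' @return List: `mask` (logical matrix over the grid), `n_cells`,
#'   `area_km2`, `mass` (mass actually enclosed), `level`, and `polygons`,
#'   a list of data frames `lon`, `lat` tracing the boundary.
#' @export
ud_contour <- function(ud, level = 0.5) {
  stopifnot(inherits(ud, "cpf_ud"))
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  m <- as.vector(ud$mass)
  o <- order(m, decreasing = TRUE)
  cum <- cumsum(m[o])
  k <- which(cum >= level)[1]
  mask <- matrix(FALSE, nrow(ud$mass), ncol(ud$mass))
  mask[o[seq_len(k)]] <- TRUE
  thr <- m[o[k]]
  cl <- if (length(ud$x) >= 2 && length(ud$y) >= 2)
    grDevices::contourLines(ud$x, ud$y, ud$mass, levels = thr)
  else list()
  polys <- lapply(cl, function(p) {
    ll <- unproject_aeq(cbind(p$x, p$y), ud$colony)
    data.frame(lon = ll[, "lon"], lat = ll[, "lat"])
  })
  list(mask = mask, n_cells = k, area_km2 = k * ud$cell_km^2,
       mass = cum[k], level = level, polygons = polys)
}

#' Distance-binned frequency histogram of dive events
#'
#' Counts events in half-open `[k*bin, (k+1)*bin)` km bins along either the
#' colony-distance axis or the signed distance to the distal point (negative
#' = outbound, positive = inbound; the distal point itself, at 0, falls in
#' the first non-negative bin). On the colony axis, counts are optionally
#' split by leg.
#'
#' @param events Data frame with `colony_dist_km` and, as needed,
#'   `distal_signed_km` and `leg`; or a bare numeric vector of distances.
#' @param bin_km Bin width in km (default 5).
#' @param axis `"colony"` or `"distal_signed"`.
#' @param by_leg Split colony-axis counts by leg (requires a `leg` column).
#' @return Data frame `bin_lo`, `bin_hi`, `count` (plus per-leg columns when
#'   `by_leg`); bins with zero events inside the observed range are kept.
#' @export
bin_by_distance <- function(events, bin_km = 5,
                            axis = c("colony", "distal_signed"),
                            by_leg = FALSE) {
  axis <- match.arg(axis)
  if (is.numeric(events)) events <- if (axis == "colony")
    data.frame(colony_dist_km = events) else
    data.frame(distal_signed_km = events)
  v <- if (axis == "colony") events$colony_dist_km else events$distal_signed_km
  if (length(v) == 0L)
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  idx <- floor(v / bin_km)
  rng <- seq(min(idx), max(idx))
  out <- data.frame(bin_lo = rng * bin_km, bin_hi = (rng + 1) * bin_km)
  out$count <- as.integer(table(factor(idx, levels = rng)))
  if (by_leg && axis == "colony" && "leg" %in% names(events)) {
    for (l in levels(factor(events$leg))) {
      out[[paste0("count_", l)]] <-
        as.integer(table(factor(idx[events$leg == l], levels = rng)))
    }
  }
  out
}
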