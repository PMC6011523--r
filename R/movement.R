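#' Define a space-time voxel grid
#'
#' A regular grid of half-open spatial cells (default 100 m x 100 m)
#' crossed with time-of-day bins (default 10 min) that exactly tile the
#' 24-h cycle.
#'
#' @param xlim,ylim Length-2 spatial extents (m); expanded if needed so an
#'   integer number of cells fits.
#' @param cell Spatial cell size (m).
#' @param t_bin Time-of-day bin (minutes); must divide 24 h exactly.
#' @return Object of class `voxel_grid` with cell edge/centre vectors.
#' @export
voxel_grid <- function(xlim, ylim, cell = 100, t_bin = 10) {
  stopifnot(cell > 0, t_bin > 0)
  if ((24 * 60) %% t_bin != 0)
    stop("time bin must divide 24 h exactly")
  nx <- max(1L, ceiling(diff(xlim) / cell))
  ny <- max(1L, ceiling(diff(ylim) / cell))
  nt <- as.integer(24 * 60 / t_bin)
  structure(list(
    x0 = xlim[1], y0 = ylim[1], cell = cell, t_bin = t_bin,
    nx = nx, ny = ny, nt = nt,
    xb = xlim[1] + cell * (0:nx), yb = ylim[1] + cell * (0:ny),
    xc = xlim[1] + cell * (seq_len(nx) - 0.5),
    yc = ylim[1] + cell * (seq_len(ny) - 0.5)),
    class = "voxel_grid")
}

#' Brownian bridge parameters
#'
#' @param sigma_loc Location error SD in metres (default 300 m, the
#'   average receiver detection range).
#' @param sigma_m2 Brownian motion variance (m^2/s); estimated from data
#'   if `NULL`.
#' @param max_gap Longest detection gap (s) across which a bridge is
#'   still laid (default 12 h).
#' @return Object of class `bridge_params`.
#' @export
bridge_params <- function(sigma_loc = 300, sigma_m2 = NULL, max_gap = 12 * 3600) {
  stopifnot(sigma_loc > 0, is.null(sigma_m2) || sigma_m2 >= 0, max_gap > 0)
  structure(list(sigma_loc = sigma_loc, sigma_m2 = sigma_m2,
                 max_gap = max_gap), class = "bridge_params")
}

#' Estimate the Brownian motion variance by leave-one-out likelihood
#'
#' Each odd-indexed interior detection is predicted from its two
#' neighbours under the Brownian bridge: mean at the time-weighted
#' interpolation, per-axis variance `a(1-a) T sigma_m2 + ((1-a)^2 + a^2)
#' sigma_loc^2` from the bridge and endpoint errors, plus `sigma_loc^2`
#' for the held-out detection's own location error. The motion variance
#' maximising the product of these Gaussian leave-one-out likelihoods is
#' returned.
#'
#' @param detections A `detection_series` (>= 3 rows).
#' @param sigma_loc Location error SD (m).
#' @param upper Upper search bound for `sigma_m2` (m^2/s).
#' @return Estimated `sigma_m2` (m^2/s, >= 0).
#' @export
estimate_motion_variance <- function(detections, sigma_loc = 300, upper = 100) {
  n <- nrow(detections)
  if (n < 3) stop("need at least 3 detections")
  o <- order(detections$time)
  tt <- detections$time[o]; x <- detections$x[o]; y <- detections$y[o]
  mid <- seq(2, n - 1, by = 2)
  a <- (tt[mid] - tt[mid - 1]) / (tt[mid + 1] - tt[mid - 1])
  keep <- is.finite(a) & a > 0 & a < 1
  mid <- mid[keep]; a <- a[keep]
  if (!length(mid)) return(0)
  T2 <- tt[mid + 1] - tt[mid - 1]
  mx <- (1 - a) * x[mid - 1] + a * x[mid + 1]
  my <- (1 - a) * y[mid - 1] + a * y[mid + 1]
  negll <- function(s2) {
    v <- a * (1 - a) * T2 * s2 + ((1 - a)^2 + a^2 + 1) * sigma_loc^2
    -sum(dnorm(x[mid], mx, sqrt(v), log = TRUE) +
           dnorm(y[mid], my, sqrt(v), log = TRUE))
  }
  opt <- optimize(negll, c(0, upper))
  # accept the boundary when the interior optimum is not better
  if (negll(0) <= opt$objective) 0 else opt$minimum
}

#' Brownian bridge density parameters at a fractional time
#'
#' Closed-form mean and per-axis variance of the bridge connecting two
#' detections, including location error at both ends:
#' mean `(1-alpha) z_a + alpha z_b`, variance
#' `alpha (1-alpha) T sigma_m2 + ((1-alpha)^2 + alpha^2) sigma_loc^2`.
#'
#' @param za,zb Length-2 endpoint coordinates (m).
#' @param ta,tb Endpoint times (s), `tb > ta`.
#' @param alpha Fraction of the interval, in `[0, 1]`.
#' @param params A [bridge_params()] with non-`NULL` `sigma_m2`.
#' @return List with `mean` (length 2) and `var` (per-axis variance).
#' @export
bridge_density <- function(za, zb, ta, tb, alpha, params) {
  if (tb <= ta) stop("tb must exceed ta")
  stopifnot(alpha >= 0, alpha <= 1, !is.null(params$sigma_m2))
  Tt <- tb - ta
  list(mean = (1 - alpha) * za + alpha * zb,
       var = alpha * (1 - alpha) * Tt * params$sigma_m2 +
         ((1 - alpha)^2 + alpha^2) * params$sigma_loc^2)
}

# Per-axis cell masses of an isotropic Gaussian over grid cell edges.
cell_probs <- function(mu, sdv, edges) {
  p <- pnorm(edges, mu, sdv)
  diff(p)
}

#' Space-time utilization distribution from detections
#'
#' Lays a Brownian bridge over every consecutive detection pair whose gap
#' does not exceed `params$max_gap`. Each bridge is cut at the absolute
#' 10-min bin boundaries it spans; for every segment the bridge Gaussian
#' is evaluated at the segment midpoint (single-point quadrature),
#' discretised exactly onto the spatial cells, weighted by the segment
#' duration, and accumulated into the time-of-day slice the segment falls
#' in (timestamps folded modulo 24 h). The full volume is normalised to
#' total mass 1; `normalize = "slice"` instead normalises each
#' time-of-day slice separately.
#'
#' @param detections A `detection_series`.
#' @param grid A [voxel_grid()].
#' @param params A [bridge_params()]; `sigma_m2 = NULL` triggers
#'   [estimate_motion_variance()].
#' @param normalize `"volume"` (default) or `"slice"`.
#' @return Object of class `spacetime_ud`: list with `grid`, `values`
#'   (array nx x ny x nt), `sigma_m2`, `normalize`, `occupancy`
#'   (seconds of bridge time per time bin).
#' @export
spacetime_ud <- function(detections, grid, params = bridge_params(),
                         normalize = c("volume", "slice")) {
  normalize <- match.arg(normalize)
  o <- order(detections$time)
  tt <- detections$time[o]; x <- detections$x[o]; y <- detections$y[o]
  if (length(tt) < 2) stop("need at least 2 detections")
  gap <- diff(tt)
  eligible <- which(gap > 0 & gap <= params$max_gap)
  if (!length(eligible))
    stop("no detection pairs within max_gap (", params$max_gap,
         " s); nothing to bridge")
  s2 <- params$sigma_m2
  if (is.null(s2))
    s2 <- if (length(tt) >= 3)
      estimate_motion_variance(detections, params$sigma_loc) else 0
  vol <- array(0, c(grid$nx, grid$ny, grid$nt))
  occ <- numeric(grid$nt)
  bin_s <- grid$t_bin * 60
  for (i in eligible) {
    ta <- tt[i]; tb <- tt[i + 1]
    cuts <- seq(floor(ta / bin_s) * bin_s, ceiling(tb / bin_s) * bin_s,
                by = bin_s)
    cuts <- unique(pmin(pmax(cuts, ta), tb))
    if (length(cuts) < 2) next
    for (sgm in seq_len(length(cuts) - 1)) {
      t0 <- cuts[sgm]; t1 <- cuts[sgm + 1]
      w <- t1 - t0
      if (w <= 0) next
      tm <- (t0 + t1) / 2
      al <- (tm - ta) / (tb - ta)
      v <- al * (1 - al) * (tb - ta) * s2 +
        ((1 - al)^2 + al^2) * params$sigma_loc^2
      sdv <- sqrt(v)
      mux <- (1 - al) * x[i] + al * x[i + 1]
      muy <- (1 - al) * y[i] + al * y[i + 1]
      px <- cell_probs(mux, sdv, grid$xb)
      py <- cell_probs(muy, sdv, grid$yb)
      bin <- (floor((tm %% 86400) / bin_s)) %% grid$nt + 1
      vol[, , bin] <- vol[, , bin] + w * (px %o% py)
      occ[bin] <- occ[bin] + w
    }
  }
  if (normalize == "volume") {
    tot <- sum(vol)
    if (tot <= 0) stop("all bridge mass fell outside the grid")
    vol <- vol / tot
  } else {
    for (b in seq_len(grid$nt)) {
      m <- sum(vol[, , b])
      if (m > 0) vol[, , b] <- vol[, , b] / m
    }
    vol <- vol / sum(vol)
  }
  structure(list(grid = grid, values = vol, sigma_m2 = s2,
                 normalize = normalize, occupancy = occ),
            class = "spacetime_ud")
}

#' Planar (2-D) utilization distribution
#'
#' Projects a space-time volume onto the two geographic dimensions by
#' summing over time-of-day bins and renormalising.
#'
#' @param volume A `spacetime_ud`.
#' @return Object of class `planar_ud`: list with `grid` and `values`
#'   (nx x ny, mass 1).
#' @export
planar_ud <- function(volume) {
  m <- apply(volume$values, c(1, 2), sum)
  structure(list(grid = volume$grid, values = m / sum(m)),
            class = "planar_ud")
}

#' Cells of a cumulative-mass contour
#'
#' Smallest set of cells — greedy by descending mass with a deterministic
#' index tie-break — whose cumulative mass reaches `level`. For a
#' probability surface, `level = 0.5` gives the 50% utilization
#' distribution used to define a central place.
#'
#' @param ud A `planar_ud` (or matrix of cell masses summing to 1).
#' @param level Cumulative probability in (0, 1).
#' @return Data frame with `ix`, `iy` (cell indices), `x`, `y` (centres,
#'   if a grid is available), and `mass`.
#' @export
ud_contour <- function(ud, level = 0.5) {
  stopifnot(level > 0, level < 1)
  vals <- if (inherits(ud, "planar_ud")) ud$values else ud
  ord <- order(vals, seq_along(vals), decreasing = c(TRUE, FALSE),
               method = "radix")
  cum <- cumsum(vals[ord])
  k <- which(cum >= level * sum(vals))[1]
  sel <- ord[seq_len(k)]
  ij <- arrayInd(sel, dim(vals))
  out <- data.frame(ix = ij[, 1], iy = ij[, 2], mass = vals[sel])
  if (inherits(ud, "planar_ud")) {
    out$x <- ud$grid$xc[out$ix]
    out$y <- ud$grid$yc[out$iy]
  }
  out
}

#' Export a space-time volume (or seascape) to CSV + JSON header
#'
#' Long-format CSV (`x`, `y`, `time_bin_start_min`, `value`) restricted to
#' non-zero voxels, with a JSON sidecar recording the grid definition and
#' normalisation.
#'
#' @param volume A `spacetime_ud` or `activity_seascape`.
#' @param path Output CSV path; the sidecar is `paste0(path, ".json")`.
#' @param keep_zero Keep zero voxels too?
#' @return `path`, invisibly.
#' @export
write_volume_csv <- function(volume, path, keep_zero = FALSE) {
  g <- volume$grid
  idx <- if (keep_zero) which(volume$values >= 0) else which(volume$values != 0)
  ij <- arrayInd(idx, dim(volume$values))
  d <- data.frame(x = g$xc[ij[, 1]], y = g$yc[ij[, 2]],
                  time_bin_start_min = (ij[, 3] - 1) * g$t_bin,
                  value = volume$values[idx])
  write.csv(d[order(d$time_bin_start_min, d$x, d$y), ], path,
            row.names = FALSE)
  jsonlite::write_json(
    list(cell_m = g$cell, t_bin_min = g$t_bin, nx = g$nx, ny = g$ny,
         nt = g$nt, x0 = g$x0, y0 = g$y0,
         normalize = if (!is.null(volume$normalize)) volume$normalize else NA,
         class = class(volume)[1]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
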