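#' Central place from the 50% utilization contour
#'
#' Defines the central place of an individual as the cells of the
#' `level` (default 50%) utilization-distribution contour.
#'
#' @param ud A `planar_ud`.
#' @param level Cumulative UD level (default 0.5).
#' @param individual Optional label.
#' @return Object of class `central_place` with `method = "ud_contour"`
#'   and `region` (the contour cell set).
#' @export
central_place_udcontour <- function(ud, level = 0.5, individual = NA) {
  region <- ud_contour(ud, level)
  structure(list(method = "ud_contour", region = region,
                 cell = ud$grid$cell, level = level,
                 individual = individual, flag = NULL),
            class = "central_place")
}

#' Central place from the dominant receiver with a buffer
#'
#' Defines the core area as a disc of radius `buffer` centred on the
#' receiver that logged the largest share of an individual's detections.
#' If that share is below `share_threshold` (inclusive at the threshold)
#' the result is flagged `"below_threshold"`. Ties between receivers are
#' broken lexicographically by receiver id.
#'
#' @param detections A `detection_series`.
#' @param buffer Disc radius (m, default 1000).
#' @param share_threshold Required detection share (default 0.8).
#' @param individual Optional label.
#' @return Object of class `central_place` with `method =
#'   "receiver_buffer"` and `region` = list(centre, radius).
#' @export
central_place_receiver <- function(detections, buffer = 1000,
                                   share_threshold = 0.8, individual = NA) {
  if (nrow(detections) == 0) stop("no detections")
  counts <- table(detections$receiver_id)
  share <- as.numeric(counts) / sum(counts)
  ids <- names(counts)
  best <- ids[order(-share, ids)][1]
  row <- which(detections$receiver_id == best)[1]
  structure(list(method = "receiver_buffer",
                 region = list(centre = c(detections$x[row], detections$y[row]),
                               radius = buffer),
                 receiver_id = best,
                 share = max(share),
                 individual = individual,
                 flag = if (max(share) < share_threshold) "below_threshold"
                        else NULL),
            class = "central_place")
}

# Distance from points to the boundary of a central place region;
# 0 for points inside.
cp_distance <- function(place, x, y) {
  if (place$method == "receiver_buffer") {
    d <- sqrt((x - place$region$centre[1])^2 + (y - place$region$centre[2])^2)
    pmax(0, d - place$region$radius)
  } else {
    half <- place$cell / 2
    out <- rep(Inf, length(x))
    for (i in seq_len(nrow(place$region))) {
      dx <- pmax(0, abs(x - place$region$x[i]) - half)
      dy <- pmax(0, abs(y - place$region$y[i]) - half)
      out <- pmin(out, sqrt(dx^2 + dy^2))
    }
    out
  }
}

#' Diel displacement series from a central place
#'
#' Folds all detections onto the 24-h cycle and averages, per hourly bin,
#' the distance from each detection to the boundary of the individual's
#' central place (0 for detections inside it).
#'
#' @param detections A `detection_series`.
#' @param place A `central_place`.
#' @param bin_hours Bin width in hours (default 1; must divide 24).
#' @return Object of class `displacement_series`: data frame with `hour`
#'   (bin start), `mean_m`, `n`. Bins with no detections have `NA` mean.
#' @export
displacement_series <- function(detections, place, bin_hours = 1) {
  if (nrow(detections) == 0) stop("no detections")
  if (24 %% bin_hours != 0) stop("bin must divide 24 h")
  d <- cp_distance(place, detections$x, detections$y)
  hour <- ((detections$time / 3600) %% 24) %/% bin_hours * bin_hours
  bins <- seq(0, 24 - bin_hours, by = bin_hours)
  mean_m <- rep(NA_real_, length(bins))
  n <- integer(length(bins))
  agg <- tapply(d, factor(hour, levels = bins), mean)
  cnt <- tapply(d, factor(hour, levels = bins), length)
  mean_m[] <- as.numeric(agg)
  n[] <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  structure(data.frame(hour = bins, mean_m = mean_m, n = n),
            class = c("displacement_series", "data.frame"))
}

#' Average displacement across individuals
#'
#' Unweighted per-bin mean of several individuals' displacement series
#' (all on the same hourly bins). A bin is missing in the average only if
#' it is missing in every individual.
#'
#' @param series_list List of `displacement_series` on identical bins.
#' @return A `displacement_series` with `n` = number of individuals
#'   contributing to each bin.
#' @export
average_displacement <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  h <- series_list[[1]]$hour
  for (s in series_list)
    if (!identical(s$hour, h)) stop("displacement series bins do not match")
  M <- sapply(series_list, function(s) s$mean_m)
  M <- matrix(M, nrow = length(h))
  mean_m <- rowMeans(M, na.rm = TRUE)
  n_ind <- rowSums(!is.na(M))
  mean_m[n_ind == 0] <- NA_real_
  structure(data.frame(hour = h, mean_m = mean_m, n = n_ind),
            class = c("displacement_series", "data.frame"))
}

# Cyclic linear interpolation of an hourly activity curve onto the
# midpoints of the grid's time-of-day bins.
interp_curve <- function(curve, grid) {
  h <- curve$hour; p <- curve$p_state2
  if (anyNA(p)) stop("activity curve contains missing probabilities")
  hh <- c(h, h[1] + 24)
  pp <- c(p, p[1])
  mid <- ((seq_len(grid$nt) - 0.5) * grid$t_bin) / 60
  # shift midpoints into [h1, h1 + 24)
  mid2 <- h[1] + (mid - h[1]) %% 24
  approx(hh, pp, xout = mid2, rule = 2)$y
}

#' Fuse a space-time UD with an activity curve into an activity seascape
#'
#' Multiplies every voxel of the movement volume by the probability of
#' the high-activity state at that voxel's time of day (the curve is
#' cyclically interpolated to the grid's time bins). No renormalisation:
#' the seascape is movement probability weighted by activity, bounded
#' above by the UD voxelwise.
#'
#' @param volume A `spacetime_ud`.
#' @param curve An `activity_curve` (hourly), or a numeric vector with
#'   one probability per time bin of the grid.
#' @return Object of class `activity_seascape`: list with `grid`,
#'   `values`, `p_state2` (per time bin).
#' @export
fuse_activity <- function(volume, curve) {
  g <- volume$grid
  if (inherits(curve, "activity_curve") || is.data.frame(curve)) {
    p <- interp_curve(curve, g)
  } else {
    p <- as.numeric(curve)
    if (length(p) != g$nt)
      stop("activity vector length (", length(p),
           ") does not match the grid's ", g$nt, " time bins")
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("activity probabilities must lie in [0, 1]")
  vals <- volume$values
  for (b in seq_len(g$nt)) vals[, , b] <- vals[, , b] * p[b]
  structure(list(grid = g, values = vals, p_state2 = p),
            class = "activity_seascape")
}

#' Group space-time volume
#'
#' Unweighted voxelwise mean of several individuals' volumes on the same
#' grid, renormalised to total mass 1.
#'
#' @param volumes List of `spacetime_ud` objects with identical grids.
#' @return A `spacetime_ud` for the group.
#' @export
group_volume <- function(volumes) {
  stopifnot(length(volumes) >= 1)
  g <- volumes[[1]]$grid
  for (v in volumes)
    if (!identical(v$grid[c("x0", "y0", "cell", "t_bin", "nx", "ny", "nt")],
                   g[c("x0", "y0", "cell", "t_bin", "nx", "ny", "nt")]))
      stop("volumes are on different grids")
  acc <- Reduce(`+`, lapply(volumes, `[[`, "values")) / length(volumes)
  structure(list(grid = g, values = acc / sum(acc),
                 sigma_m2 = NA, normalize = "volume",
                 occupancy = Reduce(`+`, lapply(volumes, `[[`, "occupancy"))),
            class = "spacetime_ud")
}

#' Filter individuals by minimum detection count
#'
#' Retains individuals with at least `min_n` detections (inclusive at the
#' boundary).
#'
#' @param detections_list Named list of `detection_series`, one per
#'   individual.
#' @param min_n Minimum detections (default 100).
#' @return List with `retained` (the filtered list) and `report` (data
#'   frame of individual, n, retained).
#' @export
min_detection_filter <- function(detections_list, min_n = 100) {
  n <- vapply(detections_list, nrow, integer(1))
  keep <- n >= min_n
  report <- data.frame(individual = if (!is.null(names(detections_list)))
    names(detections_list) else as.character(seq_along(detections_list)),
    n = n, retained = keep, row.names = NULL)
  list(retained = detections_list[keep], report = report)
}

#' Write a displacement series to CSV
#'
#' @param series A `displacement_series`.
#' @param path Output CSV path (hour, mean_m, n).
#' @export
write_displacement_csv <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write a central place description to a JSON file
#'
#' Discs are written as centre + radius; contour regions as the cell
#' polygon list, all in planar coordinates.
#'
#' @param place A `central_place`.
#' @param path Output path.
#' @export
write_central_place <- function(place, path) {
  obj <- if (place$method == "receiver_buffer")
    list(method = place$method, centre = place$region$centre,
         radius_m = place$region$radius, receiver_id = place$receiver_id,
         share = place$share, flag = place$flag)
  else
    list(method = place$method, level = place$level, cell_m = place$cell,
         cells = place$region[, c("x", "y", "mass")], flag = place$flag)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
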