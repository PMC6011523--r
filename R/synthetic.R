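#' Parameters of a synthetic central-place-foraging track
#'
#' Describes a diel central-place forager: by day the animal holds a core
#' area of radius `day_radius` around `central_place_xy`; during the
#' nightly excursion window it loops out to about `night_excursion_dist`
#' and returns. Positions are generated as a deterministic out-and-back
#' target trajectory plus mean-reverting (Ornstein-Uhlenbeck) noise.
#'
#' @param central_place_xy Length-2 planar coordinates of the central
#'   place (m).
#' @param day_radius Radius of the daytime core area (m, > 0).
#' @param night_excursion_dist Peak excursion distance from the central
#'   place (m, >= 0; 0 disables excursions).
#' @param excursion_start,excursion_end Hours of day in `[0, 24)` bounding
#'   the excursion window (may wrap midnight).
#' @param step_interval Track time step (s, > 0).
#' @param speed_mean Typical swimming speed (m/s); scales the positional
#'   noise.
#' @param seed Integer seed; the same parameters and seed give an
#'   identical track.
#' @return Object of class `cpf_params`.
#' @export
cpf_params <- function(central_place_xy = c(0, 0), day_radius = 500,
                       night_excursion_dist = 3000,
                       excursion_start = 20, excursion_end = 8,
                       step_interval = 60, speed_mean = 0.6, seed = 1) {
  stopifnot(length(central_place_xy) == 2, day_radius > 0,
            night_excursion_dist >= 0, step_interval > 0, speed_mean > 0,
            excursion_start >= 0, excursion_start < 24,
            excursion_end >= 0, excursion_end < 24)
  structure(as.list(environment()), class = "cpf_params")
}

#' Define an acoustic receiver array
#'
#' @param receiver_id Character labels, unique.
#' @param x,y Planar receiver coordinates (m).
#' @param detection_range Detection range per receiver (m, > 0; recycled).
#' @return Data frame of class `receiver_array`.
#' @export
receiver_array <- function(receiver_id, x, y, detection_range = 300) {
  receiver_id <- as.character(receiver_id)
  if (anyDuplicated(receiver_id)) stop("receiver ids must be unique")
  stopifnot(length(x) == length(receiver_id), length(y) == length(receiver_id),
            all(detection_range > 0))
  structure(data.frame(receiver_id = receiver_id, x = x, y = y,
                       detection_range = detection_range),
            class = c("receiver_array", "data.frame"))
}

# Hour-of-day membership of a possibly midnight-wrapping window [a, b).
in_hour_window <- function(hour, a, b) {
  if (a == b) rep(FALSE, length(hour))
  else if (a < b) hour >= a & hour < b
  else hour >= a | hour < b
}

#' Simulate a central-place-foraging track
#'
#' Positions are `central_place + target_offset(t) + noise(t)`. The target
#' offset is zero during day hours; within the excursion window it moves
#' out along a per-night random bearing to `night_excursion_dist` and back
#' following a half-sine profile (peak mid-window). The noise is a
#' discrete Ornstein-Uhlenbeck process (30-min relaxation, stationary SD
#' `day_radius / 3`), clamped so the animal never strays more than
#' `day_radius` from its current target.
#'
#' @param params A [cpf_params()] object.
#' @param duration Track length in days (>= 1).
#' @return Object of class `track`: data frame with `time` (s since
#'   start), `x`, `y` (m).
#' @export
simulate_cpf_track <- function(params, duration = 30) {
  stopifnot(inherits(params, "cpf_params"))
  if (duration < 1) stop("duration must be at least 1 day")
  dt <- params$step_interval
  tt <- seq(0, duration * 86400 - dt, by = dt)
  hour <- (tt / 3600) %% 24
  n <- length(tt)

  a <- params$excursion_start; b <- params$excursion_end
  wlen <- if (a <= b) b - a else 24 - a + b   # window length, hours
  in_win <- in_hour_window(hour, a, b)
  # phase in [0, 1] through the excursion window
  phase <- ifelse(hour >= a, hour - a, hour + 24 - a) / max(wlen, 1e-9)
  target_dist <- ifelse(in_win & params$night_excursion_dist > 0,
                        params$night_excursion_dist * sin(pi * phase), 0)
  # one bearing per night: nights indexed by the day on which the window opened
  night_id <- floor((tt / 3600 - a) / 24)

  set.seed(params$seed)
  n_nights <- length(unique(night_id))
  bearings <- runif(n_nights, 0, 2 * pi)
  names(bearings) <- as.character(sort(unique(night_id)))
  th <- bearings[as.character(night_id)]

  # OU noise: relaxation tau = 30 min, stationary sd = day_radius / 3
  tau <- 1800
  phi <- exp(-dt / tau)
  ssd <- params$day_radius / 3
  innov_sd <- ssd * sqrt(1 - phi^2)
  ex <- ey <- numeric(n)
  zx <- rnorm(n, 0, innov_sd); zy <- rnorm(n, 0, innov_sd)
  ex[1] <- rnorm(1, 0, ssd); ey[1] <- rnorm(1, 0, ssd)
  for (i in 2:n) {
    ex[i] <- phi * ex[i - 1] + zx[i]
    ey[i] <- phi * ey[i - 1] + zy[i]
  }
  # clamp noise radius so |pos - target| <= day_radius always
  r <- sqrt(ex^2 + ey^2)
  over <- r > params$day_radius
  if (any(over)) {
    f <- params$day_radius / r[over]
    ex[over] <- ex[over] * f; ey[over] <- ey[over] * f
  }
  x <- params$central_place_xy[1] + target_dist * cos(th) + ex
  y <- params$central_place_xy[2] + target_dist * sin(th) + ey
  structure(data.frame(time = tt, x = x, y = y), class = c("track", "data.frame"))
}

#' Simulate acoustic detections of a track on a receiver array
#'
#' One candidate transmission ("ping") is emitted every `ping_interval`
#' seconds at the interpolated track position. Each receiver within its
#' detection range logs the ping independently with probability
#' `p_detect` (optionally decaying linearly to zero at the range edge).
#' Detections are recorded at the receiver's coordinates, as for real
#' omni-directional receivers.
#'
#' @param track A [simulate_cpf_track()] track.
#' @param array A [receiver_array()].
#' @param ping_interval Seconds between transmissions (> 0).
#' @param p_detect Detection probability within range (default 1).
#' @param distance_decay Logical: scale `p_detect` by
#'   `1 - d/detection_range`?
#' @param individual_id Label stored with the detections.
#' @param seed Integer seed.
#' @return Object of class `detection_series`: data frame with
#'   `individual_id`, `time` (s), `receiver_id`, `x`, `y`.
#' @export
simulate_detections <- function(track, array, ping_interval = 120,
                                p_detect = 1, distance_decay = FALSE,
                                individual_id = "ind1", seed = 1) {
  stopifnot(ping_interval > 0)
  empty <- data.frame(individual_id = character(), time = numeric(),
                      receiver_id = character(), x = numeric(), y = numeric())
  if (nrow(array) == 0)
    return(structure(empty, class = c("detection_series", "data.frame")))
  tp <- seq(min(track$time), max(track$time), by = ping_interval)
  px <- approx(track$time, track$x, tp)$y
  py <- approx(track$time, track$y, tp)$y
  set.seed(seed)
  rows <- vector("list", nrow(array))
  for (j in seq_len(nrow(array))) {
    d <- sqrt((px - array$x[j])^2 + (py - array$y[j])^2)
    pr <- ifelse(d <= array$detection_range[j], p_detect, 0)
    if (distance_decay)
      pr <- pr * pmax(0, 1 - d / array$detection_range[j])
    hit <- runif(length(tp)) < pr
    if (any(hit))
      rows[[j]] <- data.frame(individual_id = individual_id,
                              time = tp[hit],
                              receiver_id = array$receiver_id[j],
                              x = array$x[j], y = array$y[j])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  out <- out[order(out$time, out$receiver_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("detection_series", "data.frame"))
}

#' Simulate ODBA from a covariate-driven 2-state HMM
#'
#' Generative twin of the fitted model: hidden states follow the
#' time-varying transition matrices implied by the model and covariates,
#' observations are drawn from the state-dependent gamma densities. The
#' true state path is returned for recovery tests.
#'
#' @param spec An [hmm_spec()].
#' @param hour,tide Covariates, each of length `n` (tide `NULL` for a
#'   model without tidal terms).
#' @param n Number of 1-s observations (> 0).
#' @param seed Integer seed.
#' @return List with `odba` (numeric) and `states` (integer path).
#' @export
simulate_odba_hmm <- function(spec, hour, tide = NULL, n = length(hour),
                              seed = 1) {
  stopifnot(inherits(spec, "hmm_spec"))
  if (n <= 0) stop("n must be positive")
  if (length(hour) != n) stop("hour must have length n")
  X <- covariate_design(hour, tide, spec$harmonic_order)
  g <- trans_probs(spec, X)
  set.seed(seed)
  u <- runif(n)
  s <- as.integer(hmm_simpath_cpp(g$g12, g$g21, spec$delta, u))
  odba <- rgamma(n, shape = spec$shape[s], rate = spec$rate[s])
  list(odba = odba, states = s)
}

#' Simulate an hourly sensor series with a diel sinusoid
#'
#' `value(t) = mean + amplitude * cos(2 * pi * (hour - peak_hour) / 24) +
#' N(0, noise_sd)`; used to emulate diel depth, temperature, or swim-speed
#' signals.
#'
#' @param n Number of hourly values.
#' @param mean Series mean.
#' @param amplitude Diel half-range (>= 0).
#' @param peak_hour Hour of day at which the sinusoid peaks.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @return Data frame with `time_h` (hours since start), `hour`
#'   (hour of day), `value`.
#' @export
simulate_sensor_series <- function(n = 240, mean = 0, amplitude = 0,
                                   peak_hour = 0, noise_sd = 0, seed = 1) {
  stopifnot(amplitude >= 0, n > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  th <- seq_len(n) - 1
  hour <- th %% 24
  set.seed(seed)
  value <- mean + amplitude * cos(2 * pi * (hour - peak_hour) / 24) +
    rnorm(n, 0, noise_sd)
  data.frame(time_h = th, hour = hour, value = value)
}

# Semidiurnal (M2) tidal period in hours.
TIDAL_PERIOD_H <- 12.42

#' Tidal phase at a timestamp
#'
#' Splits a 12.42-h (M2 constituent) cycle anchored at a reference high
#' water into four equal phases: high, ebb, low, flood.
#'
#' @param t Timestamps (s, numeric).
#' @param reference_high Timestamp of a known high water (s).
#' @return Character vector of tidal phases.
#' @export
tide_state <- function(t, reference_high = 0) {
  period <- TIDAL_PERIOD_H * 3600
  phase <- ((t - reference_high) %% period) / period
  TIDAL_LEVELS[pmin(floor(phase * 4), 3) + 1]
}

#' Simulate raw tri-axial accelerometer data for a known state path
#'
#' Produces 20-Hz raw acceleration whose per-axis signal is gravity (0, 0,
#' 1 g after static orientation) plus zero-mean dynamic oscillation whose
#' amplitude depends on the behavioural state — a simple fixture for the
#' ODBA processing chain.
#'
#' @param states Integer state path (1/2) at 1-s resolution.
#' @param fs Sampling rate (Hz).
#' @param amp Length-2 dynamic amplitude (g) per state.
#' @param tailbeat_hz Oscillation frequency (Hz).
#' @param noise_sd Additive sensor noise SD (g).
#' @param seed Integer seed.
#' @return `raw_accel` data frame: `time` (s), `ax`, `ay`, `az` (g).
#' @export
simulate_raw_accel <- function(states, fs = 20, amp = c(0.05, 0.3),
                               tailbeat_hz = 1.2, noise_sd = 0.01, seed = 1) {
  n1 <- length(states)
  tt <- seq(0, n1 - 1 / fs, by = 1 / fs)
  a <- amp[rep(states, each = fs)]
  set.seed(seed)
  sway <- a * sin(2 * pi * tailbeat_hz * tt)
  surge <- 0.4 * a * sin(2 * pi * tailbeat_hz * tt + pi / 3)
  heave <- 0.25 * a * sin(2 * pi * 2 * tailbeat_hz * tt)
  structure(data.frame(
    time = tt,
    ax = surge + rnorm(length(tt), 0, noise_sd),
    ay = sway + rnorm(length(tt), 0, noise_sd),
    az = 1 + heave + rnorm(length(tt), 0, noise_sd)),
    class = c("raw_accel", "data.frame"))
}

#' Write detections / receivers / accelerometer / sensor CSV files
#'
#' Plain-CSV writers matching the readers in the interface module.
#' Detection timestamps are written as ISO-8601 UTC relative to an epoch
#' origin.
#'
#' @param detections,array,accel,sensor Objects produced by the
#'   simulators.
#' @param path Output file path.
#' @param origin POSIXct origin for ISO-8601 timestamps.
#' @return `path`, invisibly.
#' @name synthetic_writers
NULL

#' @rdname synthetic_writers
#' @export
write_detections_csv <- function(detections, path,
                                 origin = as.POSIXct("2013-01-01", tz = "UTC")) {
  out <- data.frame(
    individual_id = detections$individual_id,
    timestamp = format(origin + detections$time, "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    receiver_id = detections$receiver_id)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_writers
#' @export
write_receivers_csv <- function(array, path) {
  out <- data.frame(receiver_id = array$receiver_id, x_m = array$x,
                    y_m = array$y, detection_range_m = array$detection_range)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_writers
#' @export
write_accel_csv <- function(accel, path) {
  write.csv(accel[, c("time", "ax", "ay", "az")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_writers
#' @export
write_sensor_csv <- function(sensor, path) {
  write.csv(sensor, path, row.names = FALSE)
  invisible(path)
}
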