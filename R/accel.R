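#' Separate static (gravitational) and dynamic acceleration
#'
#' Estimates the static component of each axis as a centred box-car moving
#' average and the dynamic component as the residual, so that
#' `static + dynamic` reconstructs the raw signal exactly. At the series
#' edges the averaging window shrinks to the available samples rather than
#' padding with fabricated values.
#'
#' @param raw A `raw_accel` data frame (`time`, `ax`, `ay`, `az`; constant
#'   sampling interval).
#' @param window Smoothing window in seconds (default 3 s, a standard
#'   choice above shark tail-beat periods); must cover at least 2 samples
#'   and not exceed the series.
#' @return List with `static` and `dynamic`, each a data frame with
#'   `time`, `ax`, `ay`, `az`.
#' @export
separate_gravity <- function(raw, window = 3) {
  fs <- 1 / median(diff(raw$time))
  w <- as.integer(round(window * fs))
  if (w < 2) stop("window must span at least 2 samples")
  if (w > nrow(raw)) stop("window longer than the series")
  half <- floor(w / 2)
  n <- nrow(raw)
  smooth1 <- function(v) {
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  static <- data.frame(time = raw$time, ax = smooth1(raw$ax),
                       ay = smooth1(raw$ay), az = smooth1(raw$az))
  dynamic <- data.frame(time = raw$time, ax = raw$ax - static$ax,
                        ay = raw$ay - static$ay, az = raw$az - static$az)
  list(static = static, dynamic = dynamic)
}

#' Overall dynamic body acceleration at the native sampling rate
#'
#' ODBA is the sum of the absolute dynamic accelerations across the three
#' axes, a widely used proxy for activity and energy expenditure.
#'
#' @param dynamic Data frame of dynamic acceleration (`time`, `ax`, `ay`,
#'   `az`).
#' @return Data frame with `time` and non-negative `odba` (g).
#' @export
compute_odba <- function(dynamic) {
  stopifnot(all(c("ax", "ay", "az") %in% names(dynamic)))
  data.frame(time = dynamic$time,
             odba = abs(dynamic$ax) + abs(dynamic$ay) + abs(dynamic$az))
}

#' Block-average a series to a coarser resolution
#'
#' Non-overlapping block means (default 1 s); a trailing partial block is
#' dropped. Each output timestamp is the start of its block.
#'
#' @param series Data frame with `time` and one value column (e.g.
#'   `odba`).
#' @param block Block length in seconds; must be a positive multiple of
#'   the sampling interval.
#' @return Data frame on the coarser time base.
#' @export
block_average <- function(series, block = 1) {
  if (nrow(series) == 0) return(series)
  valcol <- setdiff(names(series), "time")[1]
  dt <- median(diff(series$time))
  k <- round(block / dt)
  if (k < 1 || abs(k * dt - block) > 1e-6)
    stop("block must be a positive multiple of the sampling interval")
  nb <- floor(nrow(series) / k)
  if (nb == 0) return(series[0, , drop = FALSE])
  idx <- seq_len(nb * k)
  g <- rep(seq_len(nb), each = k)
  out <- data.frame(time = series$time[(seq_len(nb) - 1) * k + 1],
                    v = as.numeric(tapply(series[[valcol]][idx], g, mean)))
  names(out)[2] <- valcol
  out
}

#' Trim the initial hours of a series
#'
#' Removes the burn-in period after tagging (default 4 h) during which the
#' animal's behaviour may still reflect capture stress.
#'
#' @param series Data frame with a `time` column (s).
#' @param hours Hours to remove from the start.
#' @return The trimmed series.
#' @export
trim_initial <- function(series, hours = 4) {
  if (nrow(series) == 0) return(series)
  out <- series[series$time >= series$time[1] + hours * 3600, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Raw acceleration to 1-s ODBA, end to end
#'
#' Convenience chain: gravity separation, ODBA, 1-s block averaging, and
#' the initial trim.
#'
#' @inheritParams separate_gravity
#' @param trim_hours Initial hours to discard.
#' @return 1-s ODBA data frame (`time`, `odba`).
#' @export
odba_pipeline <- function(raw, window = 3, trim_hours = 4) {
  dyn <- separate_gravity(raw, window)$dynamic
  trim_initial(block_average(compute_odba(dyn), 1), trim_hours)
}

#' Read an accelerometer CSV (time, ax, ay, az)
#'
#' @param path CSV path with columns `time`, `ax`, `ay`, `az`.
#' @return A `raw_accel` data frame.
#' @export
read_accel_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time", "ax", "ay", "az") %in% names(d)))
  structure(d[, c("time", "ax", "ay", "az")],
            class = c("raw_accel", "data.frame"))
}

#' Write a 1-s ODBA series to CSV
#'
#' @param odba Data frame with `time`, `odba`.
#' @param path Output CSV path.
#' @export
write_odba_csv <- function(odba, path) {
  write.csv(odba, path, row.names = FALSE)
  invisible(path)
}
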