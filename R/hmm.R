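#' Transition-probability design matrix for diel and tidal covariates
#'
#' Builds the design matrix whose rows parameterise the two off-diagonal
#' entries of the hidden-state transition matrix at each observation time.
#' Time of day enters through `harmonic_order` sine/cosine pairs (period
#' 24 h), so the transition probabilities vary smoothly and cyclically over
#' the day; tidal state enters as treatment-coded dummies with "high" as
#' the reference phase.
#'
#' @param hour Numeric vector of decimal hours of day in `[0, 24)`.
#' @param tide Optional character/factor vector of tidal phases (values in
#'   [tidal_levels()]); `NULL` omits tidal terms.
#' @param harmonic_order Integer `>= 0`: number of sin/cos harmonic pairs.
#' @return Numeric matrix with one row per observation; first column is the
#'   intercept.
#' @export
covariate_design <- function(hour, tide = NULL, harmonic_order = 2) {
  stopifnot(harmonic_order >= 0, all(is.finite(hour)))
  n <- length(hour)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (harmonic_order > 0) {
    for (k in seq_len(harmonic_order)) {
      X <- cbind(X, sin(2 * pi * k * hour / 24), cos(2 * pi * k * hour / 24))
      colnames(X)[ncol(X) - 1:0] <- paste0(c("sin", "cos"), k)
    }
  }
  if (!is.null(tide)) {
    tide <- as.character(tide)
    bad <- which(!tide %in% TIDAL_LEVELS)
    if (length(bad))
      stop("unknown tidal level at position ", bad[1], ": '", tide[bad[1]], "'")
    if (length(tide) != n) stop("hour and tide lengths differ")
    for (lev in TIDAL_LEVELS[-1]) {
      X <- cbind(X, as.numeric(tide == lev))
      colnames(X)[ncol(X)] <- paste0("tide", lev)
    }
  }
  X
}

#' Specify a 2-state hidden Markov model for ODBA
#'
#' Constructs the parametric model assumed for 1-s overall dynamic body
#' acceleration: a hidden 2-state Markov chain (state 1 = relatively low
#' activity, state 2 = relatively high activity) with gamma state-dependent
#' densities and logit-linear covariate effects on the two off-diagonal
#' transition probabilities.
#'
#' @param shape,rate Length-2 positive vectors: gamma parameters of states
#'   1 and 2.
#' @param beta12,beta21 Coefficient vectors (intercept first) for the
#'   1→2 and 2→1 transition logits, matching [covariate_design()] columns.
#' @param delta Initial state distribution (length 2, sums to 1).
#' @param harmonic_order Harmonic order of the diel terms in the design.
#' @param tidal Logical: does the design include tidal dummies?
#' @return Object of class `hmm_spec`.
#' @export
hmm_spec <- function(shape, rate, beta12, beta21, delta = c(0.5, 0.5),
                     harmonic_order = 2, tidal = FALSE) {
  stopifnot(length(shape) == 2, length(rate) == 2,
            all(shape > 0), all(rate > 0),
            length(beta12) == length(beta21),
            length(delta) == 2, all(delta >= 0),
            abs(sum(delta) - 1) < 1e-8)
  structure(list(shape = unname(as.numeric(shape)),
                 rate = unname(as.numeric(rate)),
                 beta12 = unname(as.numeric(beta12)),
                 beta21 = unname(as.numeric(beta21)),
                 delta = unname(as.numeric(delta)),
                 harmonic_order = harmonic_order,
                 tidal = tidal),
            class = "hmm_spec")
}

# Off-diagonal transition probabilities for every row of a design matrix.
trans_probs <- function(spec, X) {
  if (ncol(X) != length(spec$beta12))
    stop("covariate row length (", ncol(X), ") does not match coefficients (",
         length(spec$beta12), ")")
  list(g12 = plogis(drop(X %*% spec$beta12)),
       g21 = plogis(drop(X %*% spec$beta21)))
}

#' Transition matrix at one covariate row
#'
#' Evaluates the 2x2 state transition matrix at a single covariate row:
#' off-diagonals are inverse-logits of the linear predictors, diagonals the
#' complements, so each row sums to one by construction.
#'
#' @param spec An `hmm_spec` (or `hmm_fit`).
#' @param x Covariate row (numeric vector matching the design columns).
#' @return 2x2 row-stochastic matrix.
#' @export
transition_matrix <- function(spec, x) {
  if (inherits(spec, "hmm_fit")) spec <- spec$spec
  if (length(x) != length(spec$beta12))
    stop("covariate row length (", length(x),
         ") does not match coefficients (", length(spec$beta12), ")")
  g12 <- plogis(sum(x * spec$beta12))
  g21 <- plogis(sum(x * spec$beta21))
  matrix(c(1 - g12, g21, g12, 1 - g21), 2, 2)
}

# State-dependent gamma densities for all observations (T x 2), optionally
# on the log scale.
state_dens <- function(spec, odba, log = FALSE) {
  cbind(dgamma(odba, spec$shape[1], spec$rate[1], log = log),
        dgamma(odba, spec$shape[2], spec$rate[2], log = log))
}

#' HMM log-likelihood via the scaled forward recursion
#'
#' @param spec An `hmm_spec`.
#' @param odba Positive numeric vector of 1-s ODBA observations.
#' @param X Design matrix from [covariate_design()], one row per
#'   observation; row `t` parameterises the transition from `t - 1` to `t`.
#' @return Log-likelihood (scalar).
#' @export
hmm_loglik <- function(spec, odba, X) {
  bad <- which(!is.finite(odba))
  if (length(bad))
    stop("non-finite ODBA observation at index ", bad[1])
  if (nrow(X) != length(odba)) stop("design and observations differ in length")
  g <- trans_probs(spec, X)
  hmm_forward_cpp(state_dens(spec, odba), g$g12, g$g21, spec$delta)
}

# --- working-parameter plumbing -------------------------------------------

spec_to_working <- function(spec) {
  c(log(spec$shape), log(spec$rate), spec$beta12, spec$beta21,
    qlogis(spec$delta[2]))
}

working_to_spec <- function(w, p, harmonic_order, tidal) {
  d2 <- plogis(w[4 + 2 * p + 1])
  hmm_spec(shape = exp(w[1:2]), rate = exp(w[3:4]),
           beta12 = w[5:(4 + p)], beta21 = w[(5 + p):(4 + 2 * p)],
           delta = c(1 - d2, d2),
           harmonic_order = harmonic_order, tidal = tidal)
}

# Swap state labels (1 <-> 2) in every parameter block.
swap_states <- function(spec) {
  hmm_spec(shape = rev(spec$shape), rate = rev(spec$rate),
           beta12 = spec$beta21, beta21 = spec$beta12,
           delta = rev(spec$delta),
           harmonic_order = spec$harmonic_order, tidal = spec$tidal)
}

#' Fit the 2-state ODBA hidden Markov model by maximum likelihood
#'
#' Maximises the forward-algorithm likelihood over unconstrained working
#' parameters (log gamma shape/rate, transition-logit coefficients, initial
#' distribution logit) by quasi-Newton search from `n_restarts` randomised
#' starting points; the best converged restart is kept. States are
#' relabelled so that state 1 has the smaller ODBA mean. Zero ODBA values
#' (outside gamma support) are replaced by half the smallest positive
#' observation and counted in the output.
#'
#' @param odba Numeric vector of 1-s ODBA (non-negative).
#' @param hour Decimal hour of day per observation.
#' @param tide Optional tidal phase per observation (see [tidal_levels()]).
#' @param harmonic_order Diel harmonic order for the transition design.
#' @param n_restarts Number of randomised starts.
#' @param seed Integer seed controlling the restarts (fit is deterministic
#'   given data and seed).
#' @param tol Relative convergence tolerance passed to the optimiser.
#' @return Object of class `hmm_fit`: `spec` (fitted parameters),
#'   `loglik`, `AIC`, `vcov` (working-parameter covariance from the
#'   observed information), `convergence`, `n_restarts`, `seed`,
#'   `n_zero_replaced`, and the data dimensions.
#' @export
fit_hmm <- function(odba, hour, tide = NULL, harmonic_order = 2,
                    n_restarts = 10, seed = 1, tol = 1e-9) {
  stopifnot(length(odba) == length(hour), n_restarts >= 1)
  bad <- which(!is.finite(odba))
  if (length(bad)) stop("non-finite ODBA observation at index ", bad[1])
  if (any(odba < 0)) stop("ODBA must be non-negative")
  nzero <- sum(odba == 0)
  if (nzero) {
    if (all(odba == 0)) stop("all ODBA values are zero")
    odba[odba == 0] <- min(odba[odba > 0]) / 2
  }
  X <- covariate_design(hour, tide, harmonic_order)
  p <- ncol(X)
  tidal <- !is.null(tide)

  # Condition-free objective: outside the numerically valid region a large
  # finite penalty is returned instead of signalling, which keeps the
  # quasi-Newton line search well defined. The gamma density is evaluated
  # from its closed form with log(x) precomputed — the objective is called
  # thousands of times and this is the hot path.
  lx <- log(odba)
  nll <- function(w) {
    if (any(!is.finite(w)) || any(abs(w[1:4]) > 30)) return(1e10)
    shape <- exp(w[1:2]); rate <- exp(w[3:4])
    d2 <- plogis(w[4 + 2 * p + 1])
    g12 <- plogis(drop(X %*% w[5:(4 + p)]))
    g21 <- plogis(drop(X %*% w[(5 + p):(4 + 2 * p)]))
    dens <- cbind(
      exp((shape[1] - 1) * lx - rate[1] * odba +
            shape[1] * log(rate[1]) - lgamma(shape[1])),
      exp((shape[2] - 1) * lx - rate[2] * odba +
            shape[2] * log(rate[2]) - lgamma(shape[2])))
    ll <- hmm_forward_cpp(dens, g12, g21, c(1 - d2, d2))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # moment-based starts: split the sample at its 60th percentile
  lo <- odba[odba <= quantile(odba, 0.6)]
  hi <- odba[odba > quantile(odba, 0.6)]
  mom <- function(x) {
    m <- mean(x); v <- max(var(x), 1e-8)
    c(shape = m^2 / v, rate = m / v)
  }
  m1 <- mom(lo); m2 <- mom(hi)

  set.seed(seed)
  best <- NULL
  conv_any <- FALSE
  for (r in seq_len(n_restarts)) {
    jit <- if (r == 1) 0 else 0.4
    w0 <- c(log(c(m1["shape"], m2["shape"])) + rnorm(2, 0, jit),
            log(c(m1["rate"], m2["rate"])) + rnorm(2, 0, jit),
            c(-2 + rnorm(1, 0, jit), rnorm(p - 1, 0, jit / 2)),
            c(-2 + rnorm(1, 0, jit), rnorm(p - 1, 0, jit / 2)),
            0)
    if (!is.finite(nll(w0))) next
    opt <- tryCatch(
      optim(w0, nll, method = "BFGS",
            control = list(maxit = 500, reltol = tol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) conv_any <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !conv_any)
    stop("fit_hmm: no restart converged; no parameters are reported")

  H <- tryCatch(optim(best$par, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1))$hessian,
                error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL

  spec <- working_to_spec(best$par, p, harmonic_order, tidal)
  swapped <- FALSE
  if (spec$shape[1] / spec$rate[1] > spec$shape[2] / spec$rate[2]) {
    spec <- swap_states(spec)
    swapped <- TRUE
    if (!is.null(vc)) {
      perm <- c(2, 1, 4, 3, (4 + p + 1):(4 + 2 * p), 5:(4 + p), 4 + 2 * p + 1)
      vc <- vc[perm, perm]
      # delta logit flips sign under relabelling
      k <- 4 + 2 * p + 1
      vc[k, ] <- -vc[k, ]; vc[, k] <- -vc[, k]
    }
  }
  k <- length(best$par)
  structure(list(spec = spec, loglik = -best$value,
                 AIC = 2 * k - 2 * (-best$value),
                 vcov = vc, convergence = TRUE, swapped = swapped,
                 n_restarts = n_restarts, seed = seed,
                 n_zero_replaced = nzero, n_obs = length(odba),
                 design_cols = colnames(X)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  s <- x$spec
  cat("2-state gamma HMM fit (", x$n_obs, " obs)\n", sep = "")
  cat(sprintf("  state 1: shape %.4g rate %.4g (mean %.4g)\n",
              s$shape[1], s$rate[1], s$shape[1] / s$rate[1]))
  cat(sprintf("  state 2: shape %.4g rate %.4g (mean %.4g)\n",
              s$shape[2], s$rate[2], s$shape[2] / s$rate[2]))
  cat(sprintf("  logLik %.3f  AIC %.3f  zeros replaced %d\n",
              x$loglik, x$AIC, x$n_zero_replaced))
  invisible(x)
}

#' Decode behavioural states
#'
#' Global decoding (Viterbi most-probable path) and local state
#' probabilities (forward-backward smoothing) for an observed ODBA series
#' under a fitted or specified model.
#'
#' @param fit An `hmm_fit` or `hmm_spec`.
#' @inheritParams fit_hmm
#' @return List with `viterbi` (integer states 1/2) and `state2_prob`
#'   (smoothed probability of the high-activity state at each time).
#' @export
decode_states <- function(fit, odba, hour, tide = NULL) {
  spec <- if (inherits(fit, "hmm_fit")) fit$spec else fit
  if (any(odba <= 0)) {
    if (any(odba < 0)) stop("ODBA must be non-negative")
    odba[odba == 0] <- min(odba[odba > 0]) / 2
  }
  X <- covariate_design(hour, tide, spec$harmonic_order)
  g <- trans_probs(spec, X)
  vit <- hmm_viterbi_cpp(state_dens(spec, odba, log = TRUE),
                         g$g12, g$g21, spec$delta)
  post <- hmm_fb_cpp(state_dens(spec, odba), g$g12, g$g21, spec$delta)
  list(viterbi = as.integer(vit), state2_prob = post[, 2])
}

# Periodic stationary state-2 probability at every time bin of a 24-h cycle
# for a fixed tidal level. The stationary vector of the one-cycle product
# anchors the first bin; the remaining bins follow by propagation, since
# the periodically stationary marginals satisfy delta_{b+1} = delta_b G_{b+1}
# (numerically stable, no matrix inverses).
periodic_stationary <- function(spec, bin_minutes = 10, tide = NULL) {
  K <- as.integer(round(24 * 60 / bin_minutes))
  mid <- (seq_len(K) - 0.5) * bin_minutes / 60
  X <- covariate_design(mid, if (is.null(tide)) NULL else rep(tide, K),
                        spec$harmonic_order)
  g <- trans_probs(spec, X)
  G <- lapply(seq_len(K), function(k)
    matrix(c(1 - g$g12[k], g$g21[k], g$g12[k], 1 - g$g21[k]), 2, 2))
  # one-cycle product starting after bin 1: M = G_2 G_3 ... G_K G_1
  M <- diag(2)
  for (k in c(seq_len(K)[-1], 1L)) M <- M %*% G[[k]]
  denom <- M[1, 2] + M[2, 1]
  if (!is.finite(denom) || denom <= 0)
    stop("singular one-cycle transition product; stationary distribution undefined")
  d <- c(M[2, 1], M[1, 2]) / denom   # stationary of M = marginal at bin 1
  out <- numeric(K)
  out[1] <- d[2]
  for (b in seq_len(K)[-1]) {
    d <- drop(d %*% G[[b]])
    d <- d / sum(d)
    out[b] <- d[2]
  }
  list(bin_mid_hour = mid, p_state2 = pmin(pmax(out, 0), 1))
}

#' Diel activity-probability curve
#'
#' For each hour of day (tidal state held fixed) the probability of being
#' in the high-activity state under the periodically stationary
#' distribution of the fitted Markov chain: the one-cycle product of
#' 10-minute transition matrices started at that hour, whose stationary
#' vector gives the long-run state probabilities at that point in the
#' cycle. Confidence bounds come from a parametric bootstrap: working
#' parameters are drawn from their asymptotic normal distribution and the
#' curve recomputed for each draw.
#'
#' @param fit An `hmm_fit` (for confidence intervals) or `hmm_spec`
#'   (point curve only).
#' @param hours Hour-of-day grid (default `0:23`).
#' @param tide Single tidal level at which to hold the tidal covariate, or
#'   `NULL` for a model without tidal terms.
#' @param bin_minutes Resolution of the transition cycle (default 10 min).
#' @param n_boot Bootstrap draws for the 95% interval (0 to skip).
#' @param seed Seed for the bootstrap draws.
#' @return Object of class `activity_curve`: data frame with `hour`,
#'   `tide`, `p_state2`, `lo95`, `hi95`.
#' @export
activity_curve <- function(fit, hours = 0:23, tide = NULL,
                           bin_minutes = 10, n_boot = 1000, seed = 1) {
  spec <- if (inherits(fit, "hmm_fit")) fit$spec else fit
  ps <- periodic_stationary(spec, bin_minutes, tide)
  K <- length(ps$p_state2)
  bin_of <- function(h) (floor((h %% 24) * 60 / bin_minutes) %% K) + 1
  est <- ps$p_state2[bin_of(hours)]
  lo <- hi <- rep(NA_real_, length(hours))
  if (n_boot > 0 && inherits(fit, "hmm_fit") && !is.null(fit$vcov)) {
    w0 <- spec_to_working(spec)
    V <- (fit$vcov + t(fit$vcov)) / 2
    ev <- eigen(V, symmetric = TRUE)
    ev$values <- pmax(ev$values, 0)
    L <- ev$vectors %*% diag(sqrt(ev$values), length(w0))
    p <- (length(w0) - 5) / 2
    set.seed(seed)
    boots <- matrix(NA_real_, n_boot, length(hours))
    for (b in seq_len(n_boot)) {
      wb <- w0 + drop(L %*% rnorm(length(w0)))
      sb <- tryCatch(working_to_spec(wb, p, spec$harmonic_order, spec$tidal),
                     error = function(e) NULL)
      if (is.null(sb)) next
      pb <- tryCatch(periodic_stationary(sb, bin_minutes, tide)$p_state2,
                     error = function(e) NULL)
      if (is.null(pb)) next
      boots[b, ] <- pb[bin_of(hours)]
    }
    qs <- apply(boots, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  structure(data.frame(hour = hours,
                       tide = if (is.null(tide)) NA_character_ else tide,
                       p_state2 = est, lo95 = lo, hi95 = hi),
            class = c("activity_curve", "data.frame"))
}

#' Mean bout (dwell) duration per state
#'
#' Mean length of maximal runs of each decoded state, in seconds for a
#' 1-s-resolution path. A state that never occurs is reported as `NA`.
#'
#' @param path Integer vector of decoded states (1/2).
#' @return Named numeric vector `c(state1 = ..., state2 = ...)`.
#' @export
dwell_time_summary <- function(path) {
  if (length(path) == 0) stop("empty state path")
  r <- rle(as.integer(path))
  c(state1 = if (any(r$values == 1)) mean(r$lengths[r$values == 1]) else NA_real_,
    state2 = if (any(r$values == 2)) mean(r$lengths[r$values == 2]) else NA_real_)
}

#' Percent of time per behavioural state
#'
#' @param path Integer vector of decoded states (1/2).
#' @return Named numeric vector of percentages summing to 100.
#' @export
state_occupancy <- function(path) {
  if (length(path) == 0) stop("empty state path")
  c(state1 = 100 * mean(path == 1), state2 = 100 * mean(path == 2))
}

#' Write a fitted HMM to a structured text file
#'
#' @param fit An `hmm_fit`.
#' @param path Output file (JSON).
#' @export
write_hmm_fit <- function(fit, path) {
  obj <- list(shape = fit$spec$shape, rate = fit$spec$rate,
              beta12 = fit$spec$beta12, beta21 = fit$spec$beta21,
              delta = fit$spec$delta,
              harmonic_order = fit$spec$harmonic_order,
              tidal = fit$spec$tidal, design_cols = fit$design_cols,
              loglik = fit$loglik, AIC = fit$AIC,
              convergence = fit$convergence, n_restarts = fit$n_restarts,
              seed = fit$seed, n_zero_replaced = fit$n_zero_replaced,
              n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write an activity curve to CSV
#'
#' @param curve An `activity_curve`.
#' @param path Output CSV path (columns hour, tide, p_state2, lo95, hi95).
#' @export
write_activity_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
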