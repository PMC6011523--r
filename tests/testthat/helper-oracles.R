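# Independent oracles and small fixtures shared across the suite.
# The oracles deliberately avoid the package's recursions: likelihoods by
# full path enumeration, decoding by exhaustive argmax.

# Log path-probabilities of every 2^T state path (vectorised over paths,
# looping only over time). Shared by the enumeration oracles below.
brute_path_logprobs <- function(spec, odba, X) {
  Tn <- length(odba)
  g12 <- plogis(drop(X %*% spec$beta12))
  g21 <- plogis(drop(X %*% spec$beta21))
  ld <- cbind(dgamma(odba, spec$shape[1], spec$rate[1], log = TRUE),
              dgamma(odba, spec$shape[2], spec$rate[2], log = TRUE))
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  lp <- log(spec$delta[paths[, 1]]) + ld[cbind(1, paths[, 1])]
  for (t in 2:Tn) {
    from1 <- paths[, t - 1] == 1
    to2 <- paths[, t] == 2
    pr <- ifelse(from1,
                 ifelse(to2, g12[t], 1 - g12[t]),
                 ifelse(to2, 1 - g21[t], g21[t]))
    lp <- lp + log(pr) + ld[cbind(t, paths[, t])]
  }
  list(paths = paths, lp = lp)
}

# Log-likelihood of a 2-state HMM by summing over all 2^T state paths.
brute_loglik <- function(spec, odba, X) {
  lp <- brute_path_logprobs(spec, odba, X)$lp
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Most probable path by exhaustive argmax over all 2^T paths.
brute_viterbi <- function(spec, odba, X) {
  e <- brute_path_logprobs(spec, odba, X)
  as.integer(e$paths[which.max(e$lp), ])
}

# Row-wise cumulative sums without per-row apply().
rowwise_cumsum <- function(W) {
  for (j in 2:ncol(W)) W[, j] <- W[, j - 1] + W[, j]
  W
}

# Random, numerically tame HMM spec plus matching covariates.
random_spec_and_data <- function(Tn, tidal = FALSE, harmonic_order = 1) {
  shape <- runif(2, 0.8, 6)
  rate <- sort(runif(2, 2, 30), decreasing = TRUE)
  p <- 1 + 2 * harmonic_order + if (tidal) 3 else 0
  spec <- hmm_spec(shape = sort(shape), rate = rate,
                   beta12 = runif(p, -1.5, 1.5),
                   beta21 = runif(p, -1.5, 1.5),
                   delta = {
                     d <- runif(1, 0.1, 0.9); c(d, 1 - d)
                   },
                   harmonic_order = harmonic_order, tidal = tidal)
  hour <- runif(Tn, 0, 24)
  tide <- if (tidal) sample(tidal_levels(), Tn, replace = TRUE) else NULL
  odba <- rgamma(Tn, 2, 8) + 1e-4
  list(spec = spec, hour = hour, tide = tide, odba = odba,
       X = covariate_design(hour, tide, harmonic_order))
}

# Spec with a memoryless transition structure (eta21 = -eta12): both rows
# of every transition matrix are identical, so states are independent
# across time and P(state 2 at t) = plogis(eta12 . x_t) exactly.
memoryless_spec <- function(beta = c(0.3, 1.0, 0.4), harmonic_order = 1) {
  hmm_spec(shape = c(2, 6), rate = c(25, 10),
           beta12 = beta, beta21 = -beta,
           delta = c(0.5, 0.5), harmonic_order = harmonic_order)
}

# Toy planar UD matrix with known masses.
toy_ud_matrix <- function(vals, nx, ny) {
  m <- matrix(vals, nx, ny)
  m / sum(m)
}
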