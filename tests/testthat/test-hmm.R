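test_that("transition matrices are logistic in the covariates and row-stochastic", {
  spec <- hmm_spec(shape = c(2, 5), rate = c(20, 10),
                   beta12 = c(0, 0, 0), beta21 = c(0, 0, 0),
                   harmonic_order = 1)
  G <- transition_matrix(spec, c(1, 0.3, -0.7))
  expect_equal(G, matrix(0.5, 2, 2))

  spec2 <- hmm_spec(shape = c(2, 5), rate = c(20, 10),
                    beta12 = -2, beta21 = -2, harmonic_order = 0)
  G2 <- transition_matrix(spec2, 1)
  expect_equal(G2[1, 2], 1 / (1 + exp(2)), tolerance = 1e-12)
  expect_equal(G2[2, 1], 1 / (1 + exp(2)), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    sp <- hmm_spec(shape = c(1, 2), rate = c(9, 3),
                   beta12 = rnorm(3, 0, 2), beta21 = rnorm(3, 0, 2),
                   harmonic_order = 1)
    G <- transition_matrix(sp, c(1, rnorm(2)))
    expect_equal(rowSums(G), c(1, 1), tolerance = 1e-12)
    expect_true(all(G > 0 & G < 1))
  }
  expect_error(transition_matrix(spec, c(1, 2)), "covariate row length")
})

test_that("forward log-likelihood: single-step mixture and label-swap symmetry", {
  spec <- hmm_spec(shape = c(2, 5), rate = c(20, 10),
                   beta12 = c(-1, 0.5), beta21 = c(-2, 0.1),
                   delta = c(0.3, 0.7), harmonic_order = 0)
  spec$harmonic_order <- 0
  x <- 0.25
  X <- matrix(c(1, 0.4), 1, 2)
  ll <- hmm_loglik(hmm_spec(shape = spec$shape, rate = spec$rate,
                            beta12 = spec$beta12, beta21 = spec$beta21,
                            delta = spec$delta, harmonic_order = 0), x, X)
  expect_equal(ll, log(0.3 * dgamma(x, 2, 20) + 0.7 * dgamma(x, 5, 10)),
               tolerance = 1e-12)

  set.seed(11)
  d <- random_spec_and_data(Tn = 30)
  ll1 <- hmm_loglik(d$spec, d$odba, d$X)
  swapped <- seascaper:::swap_states(d$spec)
  ll2 <- hmm_loglik(swapped, d$odba, d$X)
  expect_equal(ll1, ll2, tolerance = 1e-12)

  expect_error(hmm_loglik(d$spec, c(0.1, NA, 0.2), d$X[1:3, ]),
               "index 2")
})

test_that("forward log-likelihood equals the path-enumeration oracle", {
  set.seed(42)
  for (i in 1:25) {
    Tn <- sample(2:10, 1)
    d <- random_spec_and_data(Tn, tidal = (i %% 3 == 0))
    ll <- hmm_loglik(d$spec, d$odba, d$X)
    expect_equal(ll, brute_loglik(d$spec, d$odba, d$X), tolerance = 1e-10)
  }
})

test_that("Viterbi equals exhaustive argmax and forward-backward is a distribution", {
  set.seed(43)
  for (i in 1:25) {
    Tn <- sample(2:9, 1)
    d <- random_spec_and_data(Tn)
    dec <- decode_states(d$spec, d$odba, d$hour, d$tide)
    expect_identical(dec$viterbi, brute_viterbi(d$spec, d$odba, d$X))
    expect_true(all(dec$state2_prob >= 0 & dec$state2_prob <= 1))
  }
})

test_that("decoding recovers the true path when states are well separated", {
  spec <- hmm_spec(shape = c(50, 50), rate = c(500, 50),  # means 0.1 vs 1, tiny spread
                   beta12 = qlogis(0.05), beta21 = qlogis(0.05),
                   harmonic_order = 0)
  sim <- simulate_odba_hmm(spec, hour = rep(12, 400), n = 400, seed = 5)
  dec <- decode_states(spec, sim$odba, rep(12, 400))
  expect_gte(mean(dec$viterbi == sim$states), 0.99)
})

test_that("fit_hmm is deterministic, ML-dominant, and labels state 1 as the calmer state", {
  spec <- hmm_spec(shape = c(2, 5), rate = c(20, 10),
                   beta12 = c(-1.5, 0.8), beta21 = c(-1, -0.4),
                   harmonic_order = 0)
  spec$harmonic_order <- 0
  hr <- seq(0, 24, length.out = 4000) %% 24
  X <- covariate_design(hr, harmonic_order = 0)
  # design is intercept-only but data vary over the day through beta
  sim <- simulate_odba_hmm(hmm_spec(shape = c(2, 5), rate = c(20, 10),
                                    beta12 = c(-1.5, 0.8, 0),
                                    beta21 = c(-1, -0.4, 0),
                                    harmonic_order = 1),
                           hour = hr, n = 4000, seed = 9)
  f1 <- fit_hmm(sim$odba, hr, harmonic_order = 1, n_restarts = 2, seed = 3)
  f2 <- fit_hmm(sim$odba, hr, harmonic_order = 1, n_restarts = 2, seed = 3)
  expect_identical(f1$spec, f2$spec)
  expect_identical(f1$loglik, f2$loglik)
  # maximum-likelihood dominance over the generating parameters
  gen_ll <- hmm_loglik(hmm_spec(shape = c(2, 5), rate = c(20, 10),
                                beta12 = c(-1.5, 0.8, 0),
                                beta21 = c(-1, -0.4, 0),
                                harmonic_order = 1),
                       sim$odba, covariate_design(hr, harmonic_order = 1))
  expect_gte(f1$loglik, gen_ll)
  expect_lt(f1$spec$shape[1] / f1$spec$rate[1],
            f1$spec$shape[2] / f1$spec$rate[2])
  expect_equal(f1$AIC, 2 * 11 - 2 * f1$loglik)
})

test_that("zero ODBA values are shifted into gamma support and counted", {
  set.seed(2)
  x <- rgamma(3000, 2, 10)
  x[1:17] <- 0
  f <- fit_hmm(x, hour = runif(3000, 0, 24), harmonic_order = 0,
               n_restarts = 1, seed = 1)
  expect_identical(f$n_zero_replaced, 17L)
})

test_that("activity curve of a homogeneous model is flat at the stationary distribution", {
  spec <- hmm_spec(shape = c(2, 5), rate = c(20, 10),
                   beta12 = qlogis(0.2), beta21 = qlogis(0.3),
                   harmonic_order = 0)
  cur <- activity_curve(spec, n_boot = 0)
  expect_equal(unique(round(cur$p_state2, 12)), 0.2 / (0.2 + 0.3),
               tolerance = 1e-10)
})

test_that("periodic stationary curve matches long-run frequencies of a correlated chain", {
  spec <- hmm_spec(shape = c(2, 6), rate = c(25, 10),
                   beta12 = c(-0.5, 1.2, 0.3), beta21 = c(0.2, 0.5, -0.4),
                   harmonic_order = 1)
  n <- 240000
  hr <- ((seq_len(n) - 1) * 360 / 3600) %% 24   # 6-min steps over many days
  sim <- simulate_odba_hmm(spec, hour = hr, n = n, seed = 21)
  emp <- tapply(sim$states == 2, floor(hr), mean)
  cur <- activity_curve(spec, hours = 0:23, n_boot = 0)
  # conservative bound: the chain is autocorrelated, so allow 4x binomial sd
  nh <- tabulate(floor(hr) + 1, 24)
  tol <- 4 * sqrt(cur$p_state2 * (1 - cur$p_state2) / nh)
  expect_true(all(abs(as.numeric(emp) - cur$p_state2) < pmax(tol, 0.03)))
  expect_true(all(cur$p_state2 >= 0 & cur$p_state2 <= 1))
})

test_that("dwell times and occupancy follow hand counts", {
  expect_error(dwell_time_summary(integer(0)), "empty")
  expect_equal(dwell_time_summary(rep(1:2, 10)),
               c(state1 = 1, state2 = 1))
  d <- dwell_time_summary(rep(1, 100))
  expect_equal(d[["state1"]], 100)
  expect_true(is.na(d[["state2"]]))
  expect_equal(dwell_time_summary(c(1, 1, 2, 2, 2, 1)),
               c(state1 = 1.5, state2 = 3))

  expect_equal(state_occupancy(rep(1, 10)), c(state1 = 100, state2 = 0))
  expect_equal(state_occupancy(rep(1:2, 5)), c(state1 = 50, state2 = 50))
  expect_equal(state_occupancy(c(rep(1, 777), rep(2, 223)))[["state1"]], 77.7)
})

test_that("fit serialisation writes all parameter blocks", {
  set.seed(5)
  sim <- simulate_odba_hmm(memoryless_spec(), hour = runif(3000, 0, 24),
                           n = 3000, seed = 2)
  f <- fit_hmm(sim$odba, runif(3000, 0, 24), harmonic_order = 1,
               n_restarts = 1, seed = 1)
  path <- tempfile(fileext = ".json")
  write_hmm_fit(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$shape, f$spec$shape, tolerance = 1e-12)
  expect_equal(back$beta12, f$spec$beta12, tolerance = 1e-12)
  expect_equal(back$loglik, f$loglik, tolerance = 1e-10)
})
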