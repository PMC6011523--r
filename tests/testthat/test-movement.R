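det_series <- function(time, x, y, id = "a") {
  structure(data.frame(individual_id = id, time = time,
                       receiver_id = "R", x = x, y = y),
            class = c("detection_series", "data.frame"))
}

test_that("motion variance: zero for a stationary animal, translation invariant", {
  d <- det_series(seq(0, 6000, 600), x = rep(100, 11), y = rep(-50, 11))
  expect_equal(estimate_motion_variance(d, sigma_loc = 300), 0)
  expect_error(estimate_motion_variance(d[1:2, ]), "at least 3")

  set.seed(9)
  n <- 200
  d2 <- det_series(seq(0, by = 600, length.out = n),
                   x = cumsum(rnorm(n, 0, 20)), y = cumsum(rnorm(n, 0, 20)))
  s_a <- estimate_motion_variance(d2, sigma_loc = 10)
  d3 <- d2; d3$x <- d3$x + 5000; d3$y <- d3$y - 12345
  expect_equal(estimate_motion_variance(d3, sigma_loc = 10), s_a,
               tolerance = 1e-10)
})

test_that("motion variance recovers the generating Brownian rate", {
  s2_true <- 0.5
  dt <- 600
  est <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 500
    steps_x <- rnorm(n - 1, 0, sqrt(s2_true * dt))
    steps_y <- rnorm(n - 1, 0, sqrt(s2_true * dt))
    d <- det_series(seq(0, by = dt, length.out = n),
                    x = c(0, cumsum(steps_x)) + rnorm(n, 0, 10),
                    y = c(0, cumsum(steps_y)) + rnorm(n, 0, 10))
    estimate_motion_variance(d, sigma_loc = 10)
  }, numeric(1))
  expect_lt(abs(mean(est) - s2_true) / s2_true, 0.25)
})

test_that("bridge density follows the closed-form endpoint and symmetry limits", {
  bp <- bridge_params(sigma_loc = 300, sigma_m2 = 0.5)
  b0 <- bridge_density(c(0, 0), c(1000, 500), 0, 1800, 0, bp)
  expect_equal(b0$mean, c(0, 0))
  expect_equal(b0$var, 300^2)
  bmid <- bridge_density(c(200, -100), c(200, -100), 0, 1800, 0.5, bp)
  expect_equal(bmid$mean, c(200, -100))
  expect_error(bridge_density(c(0, 0), c(1, 1), 10, 10, 0.5, bp), "exceed")
})

test_that("bridge moments match a conditioned-random-walk Monte Carlo", {
  # random walk from noisy endpoint A conditioned to hit noisy endpoint B
  bp <- bridge_params(sigma_loc = 120, sigma_m2 = 0.4)
  za <- c(0, 0); zb <- c(800, -300); Tt <- 3600
  m <- 40; nmc <- 1e5
  set.seed(13)
  for (alpha in c(0.25, 0.5, 0.75)) {
    cf <- bridge_density(za, zb, 0, Tt, alpha, bp)
    eA <- rnorm(nmc, 0, bp$sigma_loc); eB <- rnorm(nmc, 0, bp$sigma_loc)
    A <- za[1] - eA; B <- zb[1] - eB
    dt <- Tt / m
    W <- matrix(rnorm(nmc * m, 0, sqrt(bp$sigma_m2 * dt)), nmc, m)
    W <- rowwise_cumsum(W)               # unconstrained walk increments
    k <- round(alpha * m)
    # pin the walk to B at step m (Gaussian bridge of the random walk)
    pos <- A + W[, k] - (k / m) * (W[, m] - (B - A))
    err <- abs(mean(pos) - cf$mean[1])
    expect_lt(err, 3 * sd(pos) / sqrt(nmc))
    verr <- abs(var(pos) - cf$var)
    expect_lt(verr, 3 * var(pos) * sqrt(2 / (nmc - 1)))
  }
})

test_that("two detections produce mass 1 confined to the time bins they span", {
  g <- voxel_grid(c(-1000, 1000), c(-1000, 1000), cell = 100, t_bin = 10)
  d <- det_series(c(5 * 60, 35 * 60), x = c(-200, 300), y = c(0, 100))
  v <- spacetime_ud(d, g, bridge_params(sigma_loc = 100, sigma_m2 = 0.1))
  expect_equal(sum(v$values), 1, tolerance = 1e-6)
  occupied <- which(apply(v$values, 3, sum) > 0)
  expect_identical(occupied, 1:4)  # 05:00-35:00 spans bins 1..4
  expect_true(all(v$values >= 0))
})

test_that("stationary detections concentrate the planar UD at the receiver", {
  g <- voxel_grid(c(-2000, 2000), c(-2000, 2000), cell = 100, t_bin = 10)
  tt <- seq(0, 5 * 86400, by = 1800)
  d <- det_series(tt, x = rep(0, length(tt)), y = rep(0, length(tt)))
  v <- spacetime_ud(d, g, bridge_params(sigma_loc = 300, sigma_m2 = 0))
  p <- planar_ud(v)
  within <- outer(abs(p$grid$xc) <= 600, abs(p$grid$yc) <= 600, "&")
  expect_gt(sum(p$values[within]), 0.95)
  expect_equal(sum(p$values), 1, tolerance = 1e-9)
})

test_that("the time marginal is proportional to per-bin bridge occupancy", {
  g <- voxel_grid(c(-3000, 3000), c(-3000, 3000), cell = 200, t_bin = 10)
  d <- det_series(c(0, 1200, 4200), x = c(0, 100, -200), y = c(0, 0, 300))
  v <- spacetime_ud(d, g, bridge_params(sigma_loc = 150, sigma_m2 = 0.2))
  tm <- apply(v$values, 3, sum)
  expect_equal(tm, v$occupancy / sum(v$occupancy), tolerance = 1e-6)
})

test_that("volumes are invariant to whole-day timestamp shifts", {
  g <- voxel_grid(c(-1500, 1500), c(-1500, 1500), cell = 150, t_bin = 20)
  set.seed(4)
  tt <- sort(runif(40, 0, 2 * 86400))
  d <- det_series(tt, x = rnorm(40, 0, 300), y = rnorm(40, 0, 300))
  d24 <- d; d24$time <- d24$time + 86400
  v1 <- spacetime_ud(d, g, bridge_params(sigma_loc = 200, sigma_m2 = 0.3))
  v2 <- spacetime_ud(d24, g, bridge_params(sigma_loc = 200, sigma_m2 = 0.3))
  expect_equal(v1$values, v2$values, tolerance = 1e-12)
})

test_that("doubling the location error does not shrink the spatial spread", {
  g <- voxel_grid(c(-3000, 3000), c(-3000, 3000), cell = 100, t_bin = 60)
  set.seed(6)
  tt <- seq(0, 86400, by = 1200)
  d <- det_series(tt, x = rnorm(length(tt), 0, 200),
                  y = rnorm(length(tt), 0, 200))
  iqr_x <- function(sl) {
    p <- planar_ud(spacetime_ud(d, g, bridge_params(sigma_loc = sl,
                                                    sigma_m2 = 0.1)))
    marg <- rowSums(p$values)
    cdf <- cumsum(marg)
    diff(approx(cdf, p$grid$xc, c(0.25, 0.75), ties = "ordered")$y)
  }
  expect_gte(iqr_x(600), iqr_x(300))
})

test_that("planar projection preserves mass and degenerate support", {
  g <- voxel_grid(c(0, 300), c(0, 300), cell = 100, t_bin = 360)
  v <- structure(list(grid = g, values = array(0, c(3, 3, 4)),
                      normalize = "volume"), class = "spacetime_ud")
  v$values[2, 3, 2] <- 1
  p <- planar_ud(v)
  expect_equal(p$values[2, 3], 1)
  expect_equal(sum(p$values), 1, tolerance = 1e-9)
  u <- v; u$values[] <- 1 / length(u$values)
  expect_true(all(abs(planar_ud(u)$values - 1 / 9) < 1e-12))
})

test_that("ud_contour is greedy-minimal with deterministic tie-breaks", {
  m1 <- toy_ud_matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(nrow(ud_contour(m1, 0.5)), 1)
  expect_equal(nrow(ud_contour(m1, 0.99)), 1)

  m4 <- toy_ud_matrix(rep(1, 4), 2, 2)
  expect_equal(nrow(ud_contour(m4, 0.5)), 2)

  # brute force: minimal cardinality over all subsets of 12 random cells
  set.seed(10)
  vals <- runif(12); vals <- vals / sum(vals)
  m <- matrix(vals, 3, 4)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), 12))
  for (level in c(0.2, 0.5, 0.8, 0.95)) {
    sizes <- rowSums(subsets)
    masses <- as.matrix(subsets) %*% vals
    brute_min <- min(sizes[masses >= level])
    expect_equal(nrow(ud_contour(m, level)), brute_min)
  }
})

test_that("volume CSV export round-trips the voxel values", {
  g <- voxel_grid(c(0, 400), c(0, 400), cell = 200, t_bin = 720)
  d <- det_series(c(0, 1800, 3600), x = c(100, 300, 100),
                  y = c(100, 100, 300))
  v <- spacetime_ud(d, g, bridge_params(sigma_loc = 100, sigma_m2 = 0))
  td <- withr::local_tempdir()
  f <- file.path(td, "vol.csv")
  write_volume_csv(v, f)
  back <- read.csv(f)
  expect_equal(sum(back$value), sum(v$values[v$values != 0]),
               tolerance = 1e-9)
  hdr <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(hdr$cell_m, 200)
  expect_equal(hdr$nt, 2)
})
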