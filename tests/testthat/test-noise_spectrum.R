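test_that("detrending reproduces its model class exactly", {
  n <- 16
  x <- rep(1:n, each = n); y <- rep(1:n, times = n)
  poly <- matrix(3 + 0.5 * x - 0.2 * y + 0.01 * x^2, n, n, byrow = TRUE)
  expect_lt(max(abs(detrend_roi(poly))), 1e-9)
  expect_lt(max(abs(detrend_roi(matrix(42, 8, 8)))), 1e-12)
  expect_error(detrend_roi(matrix(1, 1, 1)), "degenerate")
})

test_that("detrending matches a normal-equations oracle and reduces variance", {
  set.seed(8)
  n <- 20
  ctr <- seq_len(n) - (n + 1) / 2
  xs <- rep(ctr, each = n)               # column-major: x varies per column
  ys <- rep(ctr, times = n)
  vals <- 5 + 0.8 * xs - 0.3 * ys + rnorm(n * n)
  block <- matrix(vals, n, n)
  res <- detrend_roi(block, return_fit = TRUE)
  # oracle: solve the normal equations directly
  X <- cbind(1, xs, ys, xs^2, xs * ys, ys^2)
  beta <- solve(crossprod(X), crossprod(X, vals))
  expect_equal(as.vector(res), as.vector(vals - X %*% beta),
               tolerance = 1e-9)
  expect_lt(var(as.vector(res)), var(vals))
  cf <- attr(res, "coefficients")
  expect_equal(unname(cf[1:3]), c(5, 0.8, -0.3), tolerance = 0.2)
})

test_that("white-noise NPS is flat at sigma^2*dx*dy and Parseval holds", {
  rois <- white_roi_set(32, n = 64, delta = 0.5, sigma = 10, seed = 13)
  np <- nps_2d(rois)
  expect_true(all(np$nps2d >= 0))
  expect_equal(mean(np$nps2d), 25, tolerance = 0.05)
  # exact discrete Parseval: integral == mean detrended variance
  df <- np$fx[2] - np$fx[1]
  expect_equal(sum(np$nps2d) * df^2, np$detrended_variance,
               tolerance = 1e-10)
  # and the all-zero case
  z <- nps_2d(noise_roi_set(list(matrix(0, 16, 16)), c(0.5, 0.5)))
  expect_true(all(z$nps2d == 0))
})

test_that("a single-cosine residual concentrates energy in its DFT bins", {
  n <- 64; delta <- 0.5
  k0 <- 12                       # on-bin frequency along x
  x <- 0:(n - 1)
  block <- matrix(rep(cos(2 * pi * k0 * x / n), each = n), n, n)
  np <- nps_2d(noise_roi_set(list(block), c(delta, delta)))
  f0 <- k0 / (n * delta)
  at <- abs(abs(np$fx) - f0) < 1e-9
  in_bins <- sum(np$nps2d[abs(np$fy) < 1e-9, at])
  expect_gt(in_bins / sum(np$nps2d), 0.95)
})

test_that("radial averaging matches an exhaustive binning oracle", {
  # constant isotropic NPS: every full annulus equals the constant
  fake <- structure(list(nps2d = matrix(3.5, 32, 32),
                         fx = fft_shift_axis(32, 0.5),
                         fy = fft_shift_axis(32, 0.5)),
                    class = "nps_result")
  p <- radial_average(fake)
  expect_true(all(abs(p$nps[!p$partial] - 3.5) < 1e-12))

  # tiny grid: exhaustive per-cell assignment
  set.seed(2)
  m <- matrix(runif(16), 4, 4)
  fx <- fft_shift_axis(4, 1)
  p4 <- radial_average(m, fx = fx, fy = fx)
  df <- fx[2] - fx[1]
  acc <- list()
  for (i in 1:4) for (j in 1:4) {
    rho <- sqrt(fx[i]^2 + fx[j]^2)
    if (rho == 0) next
    b <- as.character(round(rho / df))
    acc[[b]] <- c(acc[[b]], m[i, j])
  }
  for (b in names(acc)) {
    f <- as.numeric(b) * df
    expect_equal(p4$nps[abs(p4$f - f) < 1e-9], mean(acc[[b]]))
  }

  # impulse at (f0, 0) shows up only in the bin containing f0
  imp <- matrix(0, 32, 32)
  fx32 <- fft_shift_axis(32, 0.5)
  imp[which(abs(fx32) < 1e-12), which(abs(fx32 - 0.25) < 1e-9)] <- 7
  pi1 <- radial_average(imp, fx = fx32, fy = fx32)
  expect_true(all(pi1$nps[abs(pi1$f - 0.25) > 1e-9] == 0))
  expect_gt(pi1$nps[abs(pi1$f - 0.25) < 1e-9], 0)
})

test_that("NPS summaries behave as designed", {
  # isotropic triangular radial profile peaking at 0.4 /mm
  n <- 64; delta <- 0.5
  fx <- fft_shift_axis(n, delta)
  rho <- sqrt(outer(fx^2, fx^2, "+"))
  tri <- pmax(0, 1 - abs(rho - 0.4) / 0.3)
  fake <- structure(list(nps2d = tri, fx = fx, fy = fx,
                         pixel_spacing = c(delta, delta)),
                    class = "nps_result")
  s <- nps_summary(fake)
  expect_equal(s$f_peak, 0.40625, tolerance = 1 / (n * delta))  # nearest bin
  expect_true(s$defined)

  # flat spectrum: f_average ~ half the inscribed Nyquist frequency
  flat <- structure(list(nps2d = matrix(1, n, n), fx = fx, fy = fx,
                         pixel_spacing = c(delta, delta)),
                    class = "nps_result")
  sf <- nps_summary(flat)
  expect_equal(sf$f_average, 0.5, tolerance = 0.05)
  # ties in f_peak break toward the lower frequency
  expect_equal(sf$f_peak, min(radial_average(flat)$f))

  # all-zero NPS: magnitude 0, frequencies flagged undefined
  z <- structure(list(nps2d = matrix(0, 16, 16),
                      fx = fft_shift_axis(16, delta),
                      fy = fft_shift_axis(16, delta)),
                 class = "nps_result")
  sz <- nps_summary(z)
  expect_equal(sz$noise_magnitude, 0)
  expect_false(sz$defined)
  expect_true(is.na(sz$f_peak))
})

test_that("doubling the number of ROIs roughly halves estimator variance", {
  # variance of the per-bin NPS estimate across replicates, averaged over
  # all off-DC bins (stable, unlike a single-bin variance ratio)
  reps <- function(n_roi, seed0) {
    vapply(1:24, function(s) {
      np <- nps_2d(white_roi_set(n_roi, n = 32, delta = 0.5, sigma = 10,
                                 seed = seed0 + s))
      as.vector(np$nps2d)
    }, numeric(32 * 32))
  }
  off_dc <- as.vector(outer(fft_shift_axis(32, 0.5)^2,
                            fft_shift_axis(32, 0.5)^2, "+")) > 0
  v8 <- mean(apply(reps(8, 1000), 1, var)[off_dc])
  v16 <- mean(apply(reps(16, 2000), 1, var)[off_dc])
  expect_gt(v8 / v16, 1.6)
  expect_lt(v8 / v16, 2.5)
})

test_that("a Gaussian-shaped noise kernel is recovered from the NPS", {
  rho0 <- 0.35
  stk <- flat_stack(0, n = 64, n_slices = 64, delta = 0.5)
  stk <- add_correlated_noise(stk, 10, nps_kernel_gaussian(rho0), 99)
  rois <- noise_roi_set(lapply(1:64, function(k) stk$voxels[, , k]),
                        c(0.5, 0.5))
  p <- radial_average(nps_2d(rois))
  p <- p[!p$partial & p$nps > 0, ]
  # |H|^2 = exp(-rho^2/rho0^2): log-linear fit in rho^2
  fit <- lm(log(nps) ~ I(f^2), data = p, weights = p$n_cells)
  rho0_hat <- sqrt(-1 / coef(fit)[[2]])
  expect_equal(rho0_hat, rho0, tolerance = 0.05)
})
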