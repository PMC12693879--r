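freq_axis <- function(fmax, n) seq(-fmax, fmax, length.out = n)

test_that("task function satisfies its analytic identities", {
  fx <- freq_axis(3, 129)          # odd count so the axis contains 0
  tk <- task_function(5, 10, fx, fx)
  # DC value: amplitude x disc area
  i0 <- which(abs(fx) < 1e-9)
  expect_equal(tk$w[i0, i0], 10 * pi * 2.5^2)
  expect_equal(tk$w[i0, i0], 196.3495, tolerance = 1e-4)
  # radial symmetry
  expect_equal(tk$w[i0, 1], tk$w[1, i0])
  # Parseval for the disc: integral |W|^2 = C^2 * pi * r^2
  du <- fx[2] - fx[1]
  expect_equal(sum(tk$w^2) * du^2, 100 * pi * 2.5^2, tolerance = 0.02 * 1963.5)
  expect_warning(task_function(5, 10, freq_axis(0.1, 8), freq_axis(0.1, 8)),
                 "truncated")
})

test_that("task function matches a rasterized-disc DFT oracle at low rho", {
  # oracle: DFT of a finely rasterized 5 mm disc
  n <- 512; delta <- 0.25
  ax <- ((seq_len(n) - 1) - n / 2) * delta
  disc <- outer(ax^2, ax^2, "+") <= 2.5^2
  amp <- 10
  W_num <- Mod(stats::fft(amp * disc)) * delta^2
  f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * delta)
  tk <- task_function(5, amp, f, f)
  low <- abs(f) <= 0.1   # low-frequency bins along the fx axis
  expect_equal(W_num[1, low], abs(tk$w[f == 0, low]),
               tolerance = 0.01 * amp * pi * 2.5^2)
})

test_that("NPW d-prime matches the white-noise closed form within 1%", {
  fx <- freq_axis(3, 160)
  for (case in list(c(C = 10, N0 = 25), c(C = 30, N0 = 25),
                    c(C = 10, N0 = 4))) {
    tk <- task_function(5, case[["C"]], fx, fx)
    dp <- detectability_index(1, case[["N0"]], tk)
    closed <- case[["C"]] * sqrt(pi * 2.5^2 / case[["N0"]])
    expect_lt(abs(dp$dprime - closed) / closed, 0.01)
  }
})

test_that("d-prime scaling laws hold exactly", {
  fx <- freq_axis(2.5, 96)
  tk1 <- task_function(5, 10, fx, fx)
  tk2 <- task_function(5, 20, fx, fx)
  ttf <- function(rho) exp(-2 * pi^2 * 0.3^2 * rho^2)
  d1 <- detectability_index(ttf, 25, tk1)$dprime
  d2 <- detectability_index(ttf, 25, tk2)$dprime
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  # scaling the NPS by k scales d-prime by 1/sqrt(k)
  d4 <- detectability_index(ttf, 100, tk1)$dprime
  expect_equal(d4, d1 / 2, tolerance = 1e-10)
  # zero contrast: d-prime 0; zero noise: infinite sentinel
  expect_equal(detectability_index(ttf, 25,
                                   task_function(5, 0, fx, fx))$dprime, 0)
  z <- detectability_index(ttf, 0, tk1)
  expect_true(z$infinite)
  expect_identical(z$dprime, Inf)
})

test_that("pipeline d-prime matches the analytic value within 5%", {
  # simulator scenario: known Gaussian blur + white noise; the pipeline
  # (measured TTF + measured NPS) must agree with the value computed from
  # the true MTF and the true NPS level.
  g <- catphan_geometry()
  sig <- 0.3; sigma_n <- 10; delta <- 0.42
  stk <- render_module(g, "ctp404", ground_truth(blur_sigma_mm = sig),
                       n = 512, pixel_spacing = delta)
  tt <- ttf_from_insert(stk, g$inserts[[7]], taper = FALSE)
  # 128-px ROIs: detrending biases the lowest NPS bins low, and the task
  # weighting peaks there, so the d-prime grid needs fine frequency sampling
  rois <- white_roi_set(48, n = 128, delta = delta, sigma = sigma_n, seed = 6)
  np <- nps_2d(rois)
  fx <- np$fx
  tk <- task_function(5, 30, fx, np$fy)
  d_pipe <- detectability_index(tt, np, tk)$dprime
  d_true <- detectability_index(function(rho) exp(-2 * pi^2 * sig^2 * rho^2),
                                sigma_n^2 * delta^2, tk)$dprime
  expect_lt(abs(d_pipe - d_true) / d_true, 0.05)
})

test_that("d-prime comparison arithmetic reproduces the reference table", {
  tab <- dprime_reference()
  ie04_13 <- tab[tab$parameters == "Hr72 (13.3 mGy), 0.4 mm", "Acrylic"]
  ieUHR_13 <- tab[tab$parameters == "UHR Hr72 (13.5 mGy)", "Acrylic"]
  cmp <- compare_dprime(ie04_13, ieUHR_13, c("0.4 mm", "UHR"))
  expect_equal(cmp$percent, 42, tolerance = 0.2)

  ie04_5 <- tab[tab$parameters == "Hr72 (5.04 mGy), 0.4 mm", "Acrylic"]
  ieUHR_5 <- tab[tab$parameters == "UHR Hr72 (5.12 mGy)", "Acrylic"]
  expect_equal(compare_dprime(ie04_5, ieUHR_5)$percent, 13.9,
               tolerance = 0.15)

  ta04 <- tab[tab$parameters == "Br40 (11.6 mGy), 0.4 mm", ]
  taUHR <- tab[tab$parameters == "UHR Br40 (11.6 mGy)", ]
  cmp3 <- compare_dprime(ta04$Acrylic, taUHR$Acrylic)
  expect_equal(cmp3$percent, 37.3, tolerance = 0.05)
  expect_equal(cmp3$difference, 3.96, tolerance = 1e-9)
  expect_equal(compare_dprime(ta04$Air, taUHR$Air)$difference, 138.82,
               tolerance = 1e-9)

  expect_equal(compare_dprime(5, 5)$percent, 0)
  expect_warning(compare_dprime(0, 1), "undefined")
  expect_error(compare_dprime(Inf, 1), "finite")
})

test_that("HU linearity regression matches an OLS oracle", {
  # collinear pairs
  r <- hu_linearity(hu = c(0, 1, 2), mu = c(1, 2, 3))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, -1)
  expect_equal(r$r_squared, 1)

  set.seed(12)
  mu <- c(0.05, 0.17, 0.19, 0.21, 0.23, 0.35, 0.41)
  hu <- 5000 * mu - 1030 + rnorm(7, 0, 10)
  r2 <- hu_linearity(hu, mu)
  X <- cbind(1, mu)
  beta <- solve(crossprod(X), crossprod(X, hu))
  expect_equal(r2$intercept, as.numeric(beta[1]), tolerance = 1e-10)
  expect_equal(r2$slope, as.numeric(beta[2]), tolerance = 1e-10)
  expect_lt(r2$r_squared, 1)
  expect_gt(r2$r_squared, 0.99)

  expect_error(hu_linearity(1:5, rep(0.2, 5)), "degenerate")
  expect_error(hu_linearity(1:2, 1:2), "three")
})

test_that("measured insert HUs are linear in nominal attenuation", {
  # end-to-end: simulate, measure insert CT numbers, regress against the
  # mu values implied by the linear HU definition (perfect scanner)
  g <- catphan_geometry()
  tr <- ground_truth(noise_sigma_hu = 3, seed = 14)
  stk <- render_module(g, "ctp404", tr, n = 512, pixel_spacing = 0.42)
  hu <- vapply(g$inserts, function(i) insert_hu(stk, i)$mean, numeric(1))
  mu_water <- 0.19
  mu <- (vapply(g$inserts, function(i) i$nominal_hu, numeric(1)) / 1000 + 1) *
    mu_water
  res <- hu_linearity(hu, mu, vapply(g$inserts, `[[`, "", "material"))
  expect_gt(res$r_squared, 0.999)
  expect_equal(res$slope, 1000 / mu_water, tolerance = 0.02 * 1000 / mu_water)
})
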