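# Shared fixtures: a scaled-down phantom geometry for fast renders, and a
# couple of constructors used across test files. Full-size geometry tests
# use catphan_geometry() directly.

fast_geometry <- function() {
  phantom_geometry(
    phantom_radius = 40, background_hu = 90,
    inserts = list(
      insert_spec("hi", c(0, 20), 10, 590),
      insert_spec("lo", c(0, -20), 10, -410)
    ),
    ramps = list(ramp_spec(c(12, 0), c(0, 1)),
                 ramp_spec(c(-12, 0), c(0, 1))),
    uniformity_layout = list(periphery_radius_mm = 25, roi_diameter_mm = 8,
                             n_slices = 5)
  )
}

# a flat stack of given size/spacing with constant value
flat_stack <- function(value = 0, n = 64, n_slices = 1, delta = 0.5) {
  image_stack(array(value, c(n, n, n_slices)), c(delta, delta),
              seq_len(n_slices))
}

# white-noise ROI set: n_roi independent square blocks
white_roi_set <- function(n_roi, n = 64, delta = 0.5, sigma = 10, seed = 1) {
  stk <- flat_stack(0, n, n_roi, delta)
  stk <- add_correlated_noise(stk, sigma, nps_kernel_white(), seed)
  noise_roi_set(lapply(seq_len(n_roi), function(k) stk$voxels[, , k]),
                c(delta, delta))
}

# manual roi_stats for arithmetic-only tests
stats_of <- function(mean, sd = 0, n = 1) {
  structure(list(mean = mean, sd = sd, n = n), class = "roi_stats")
}

# ascending DFT frequency axis for an n-point grid with spacing delta
fft_shift_axis <- function(n, delta) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  sort(k / (n * delta))
}

# brute-force type-7 quantile (linear interpolation between order statistics)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
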