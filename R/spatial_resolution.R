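# Slice thickness from tilted wire ramps, and the target transfer function
# from circular inserts via radial ESF -> LSF -> normalised Fourier transform.

# bilinear sampling of a slice at physical (x, y) mm; x along columns
interp_bilinear <- function(sl, x, y, dx, dy) {
  cx <- x / dx; cy <- y / dy           # 0-based fractional pixel coords
  c0 <- floor(cx); r0 <- floor(cy)
  c0 <- pmin(pmax(c0, 0), ncol(sl) - 2L)
  r0 <- pmin(pmax(r0, 0), nrow(sl) - 2L)
  tx <- cx - c0; ty <- cy - r0
  i <- r0 + 1L; j <- c0 + 1L
  sl[cbind(i, j)] * (1 - tx) * (1 - ty) +
    sl[cbind(i, j + 1L)] * tx * (1 - ty) +
    sl[cbind(i + 1L, j)] * (1 - tx) * ty +
    sl[cbind(i + 1L, j + 1L)] * tx * ty
}

ramp_profile <- function(sl, dx, dy, center, direction, half_len,
                         strip_halfwidth, step) {
  u <- seq(-half_len, half_len, by = step)
  v <- seq(-strip_halfwidth, strip_halfwidth, by = step)
  perp <- c(-direction[2L], direction[1L])
  prof <- vapply(u, function(ui) {
    xs <- center[1L] + ui * direction[1L] + v * perp[1L]
    ys <- center[2L] + ui * direction[2L] + v * perp[2L]
    max(interp_bilinear(sl, xs, ys, dx, dy))
  }, numeric(1))
  list(u = u, value = prof)
}

fwhm_of_profile <- function(u, value, min_signal = 1) {
  pk <- max(value)
  base <- min(value)
  if (pk - base < min_signal)
    stop("profile never reaches half maximum (ramp missing?)")
  half <- base + (pk - base) / 2
  above <- value >= half
  if (!any(above)) stop("profile never reaches half maximum (ramp missing?)")
  if (mean(above) > 0.9)
    warning("profile is nearly saturated; FWHM may be unreliable")
  i1 <- which(above)[1L]
  i2 <- rev(which(above))[1L]
  left <- if (i1 == 1L) u[1L] else {
    u[i1 - 1L] + (half - value[i1 - 1L]) / (value[i1] - value[i1 - 1L]) *
      (u[i1] - u[i1 - 1L])
  }
  right <- if (i2 == length(u)) u[length(u)] else {
    u[i2] + (half - value[i2]) / (value[i2 + 1L] - value[i2]) *
      (u[i2 + 1L] - u[i2])
  }
  right - left
}

#' Slice thickness from tilted wire ramps
#'
#' For each ramp the along-ramp intensity profile is extracted (maximum over
#' a narrow strip across the ramp, bilinear sampling), a local background
#' estimated from two flanking parallel strips is subtracted, the full width
#' at half maximum is found by linear interpolation of the half-maximum
#' crossings, and the slice thickness is FWHM x tan(tilt). The final value
#' is the mean of the per-ramp thicknesses.
#'
#' @param stack an [image_stack()] containing the ramp slice.
#' @param ramps list of [ramp_spec()]; default taken from `geometry`.
#' @param geometry optional [phantom_geometry()] supplying ramps.
#' @param phantom_center (x, y) mm; default the image centre.
#' @param slice slice index.
#' @param half_len_mm profile half-length along the ramp.
#' @param strip_halfwidth_mm half-width of the max-projection strip.
#' @param bg_offset_mm lateral offset of the two background strips.
#' @param step_mm profile sampling step; default a tenth of a pixel.
#' @param nominal_mm optional nominal thickness; when given, a pass/fail
#'   flag against the +-0.5 mm tolerance (collimations < 1 mm) is reported.
#' @return list of class \code{"slice_thickness_result"}: `fwhm_mm`
#'   (per-ramp, in-plane), `thickness_mm` (per-ramp), `mean_thickness_mm`,
#'   `tilt_deg`, and optionally `within_tolerance`.
#' @export
slice_thickness <- function(stack, ramps = NULL, geometry = NULL,
                            phantom_center = NULL, slice = 1L,
                            half_len_mm = 12, strip_halfwidth_mm = 2.5,
                            bg_offset_mm = 6, step_mm = NULL,
                            nominal_mm = NULL) {
  if (is.null(ramps)) {
    if (is.null(geometry)) stop("supply ramps or a geometry")
    ramps <- geometry$ramps
  }
  d <- dim(stack$voxels)
  dx <- stack$pixel_spacing[1L]; dy <- stack$pixel_spacing[2L]
  if (is.null(phantom_center))
    phantom_center <- c((d[2L] - 1) / 2 * dx, (d[1L] - 1) / 2 * dy)
  if (is.null(step_mm)) step_mm <- dx / 10
  sl <- stack$voxels[, , slice]
  fwhm <- vapply(ramps, function(rp) {
    ctr <- phantom_center + rp$center
    perp <- c(-rp$direction[2L], rp$direction[1L])
    pr <- ramp_profile(sl, dx, dy, ctr, rp$direction, half_len_mm,
                       strip_halfwidth_mm, step_mm)
    bg <- (ramp_profile(sl, dx, dy, ctr + bg_offset_mm * perp, rp$direction,
                        half_len_mm, strip_halfwidth_mm, step_mm)$value +
           ramp_profile(sl, dx, dy, ctr - bg_offset_mm * perp, rp$direction,
                        half_len_mm, strip_halfwidth_mm, step_mm)$value) / 2
    fwhm_of_profile(pr$u, pr$value - bg)
  }, numeric(1))
  tilt <- vapply(ramps, function(rp) rp$tilt_deg, numeric(1))
  thick <- fwhm * tan(tilt * pi / 180)
  out <- list(fwhm_mm = fwhm, thickness_mm = thick,
              mean_thickness_mm = mean(thick), tilt_deg = tilt)
  if (!is.null(nominal_mm))
    out$within_tolerance <- abs(mean(thick) - nominal_mm) <= 0.5
  structure(out, class = "slice_thickness_result")
}

#' Edge spread function of a circular insert
#'
#' The insert centre is refined by the centroid of the thresholded insert
#' mask (threshold at the midpoint of the inner/outer plateau estimates),
#' then every pixel within `r_max` of the centre is binned by radial
#' distance (default bin width a tenth of a pixel) and bin means form the
#' ESF, oriented from the insert plateau outwards to the background
#' plateau. Pixels of all requested slices are pooled.
#'
#' @param stack an [image_stack()] of the sensitometry module.
#' @param insert an [insert_spec()].
#' @param phantom_center (x, y) mm; default the image centre.
#' @param bin_width_px radial bin width in pixels.
#' @param r_max_mm outer analysis radius; default twice the insert radius.
#' @param slices slice indices to pool; default all.
#' @param refine_center logical; centroid refinement of the insert centre.
#' @return list of class \code{"esf_curve"}: `distance_mm` (bin centres),
#'   `value` (HU), `bin_width_mm`, `center` (mm), `level_in`, `level_out`.
#' @export
esf_from_insert <- function(stack, insert, phantom_center = NULL,
                            bin_width_px = 0.1, r_max_mm = NULL,
                            slices = NULL, refine_center = TRUE) {
  d <- dim(stack$voxels)
  dx <- stack$pixel_spacing[1L]; dy <- stack$pixel_spacing[2L]
  if (is.null(phantom_center))
    phantom_center <- c((d[2L] - 1) / 2 * dx, (d[1L] - 1) / 2 * dy)
  if (is.null(slices)) slices <- seq_len(d[3L])
  r_ins <- insert$diameter / 2
  if (is.null(r_max_mm)) r_max_mm <- 2 * r_ins
  ctr <- phantom_center + insert$center
  xs <- (seq_len(d[2L]) - 1) * dx
  ys <- (seq_len(d[1L]) - 1) * dy
  X <- matrix(rep(xs, each = d[1L]), d[1L], d[2L])
  Y <- matrix(rep(ys, times = d[2L]), d[1L], d[2L])
  sl1 <- stack$voxels[, , slices[1L]]
  if (refine_center) {
    for (it in 1:2) {
      r <- sqrt((X - ctr[1L])^2 + (Y - ctr[2L])^2)
      lin <- mean(sl1[r < 0.5 * r_ins])
      lout <- mean(sl1[r > 1.4 * r_ins & r < r_max_mm])
      thr <- (lin + lout) / 2
      mask <- if (lin >= lout) sl1 > thr else sl1 < thr
      mask <- mask & r < 1.3 * r_ins
      if (!any(mask)) break
      ctr <- c(mean(X[mask]), mean(Y[mask]))
    }
  }
  r <- sqrt((X - ctr[1L])^2 + (Y - ctr[2L])^2)
  sel <- r <= r_max_mm
  bw <- bin_width_px * (dx + dy) / 2
  rr <- rep(r[sel], times = length(slices))
  vv <- unlist(lapply(slices, function(k) stack$voxels[, , k][sel]),
               use.names = FALSE)
  bin <- as.integer(floor(rr / bw))
  means <- tapply(vv, bin, mean)
  bidx <- as.integer(names(means))
  # fill radial bins left empty by the discrete grid by linear interpolation
  full <- seq(min(bidx), max(bidx))
  val <- stats::approx(bidx, as.numeric(means), xout = full)$y
  dist <- (full + 0.5) * bw
  nq <- max(4L, floor(length(val) / 4))
  level_in <- mean(val[seq_len(nq)])
  level_out <- mean(val[seq(length(val) - nq + 1L, length(val))])
  noise <- stats::sd(val[seq(length(val) - nq + 1L, length(val))])
  if (abs(level_in - level_out) < noise)
    stop("insufficient edge contrast between insert and background")
  structure(list(distance_mm = dist, value = val, bin_width_mm = bw,
                 center = ctr, level_in = level_in, level_out = level_out),
            class = "esf_curve")
}

#' Target transfer function from an ESF
#'
#' The line spread function is the finite-difference derivative of the ESF
#' over its uniform radial bins; the TTF is the modulus of its discrete
#' Fourier transform normalised to the DC component, so TTF(0) = 1 by
#' construction. An optional cosine (Tukey) half-window tapers the LSF
#' tails before the transform to suppress noise leakage; the default taper
#' width is 20 percent of the support at each end, and the taper should be
#' turned off when comparing against closed-form oracles. The LSF is
#' zero-padded for a finer frequency sampling of the continuous spectrum.
#'
#' @param esf an [esf_from_insert()] curve.
#' @param taper logical; apply the cosine taper.
#' @param taper_frac tapered fraction of the LSF support at each end.
#' @param pad_factor zero-padding factor (>= 1).
#' @return list of class \code{"ttf_result"}: `f` (1/mm, up to Nyquist of
#'   the radial binning), `ttf`, plus `f50`, `f10` and flags from
#'   [ttf_summary()].
#' @export
ttf_from_esf <- function(esf, taper = TRUE, taper_frac = 0.2,
                         pad_factor = 4) {
  v <- esf$value
  db <- esf$bin_width_mm
  lsf <- diff(v) / db
  n <- length(lsf)
  if (taper && taper_frac > 0) {
    m <- max(1L, floor(taper_frac * n))
    w <- rep(1, n)
    ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1)))
    w[seq_len(m)] <- ramp
    w[seq(n, n - m + 1L)] <- ramp
    lsf <- lsf * w
  }
  dc <- sum(lsf) * db
  if (dc == 0) stop("zero net edge step: TTF undefined")
  npad <- 2^ceiling(log2(max(pad_factor, 1) * n))
  lp <- c(lsf, rep(0, npad - n))
  spec <- Mod(stats::fft(lp)) * db
  ttf <- spec / spec[1L]
  nf <- floor(npad / 2)
  f <- (seq_len(nf + 1L) - 1L) / (npad * db)
  keep <- f <= 1 / (2 * db) + 1e-12
  out <- list(f = f[keep], ttf = ttf[seq_len(sum(keep))])
  s <- ttf_summary(out)
  out$f50 <- s$f50; out$f10 <- s$f10
  out$f50_flag <- s$f50_flag; out$f10_flag <- s$f10_flag
  structure(out, class = "ttf_result")
}

#' TTF resolution summaries f50 and f10
#'
#' First downward crossings of TTF = 0.5 and 0.1, linearly interpolated
#' between frequency samples. When the TTF never falls below a threshold
#' within the computed range the value is NA and flagged `">Nyquist"`.
#'
#' @param ttf a `ttf_result` (or list with `f` and `ttf`).
#' @return list of class \code{"ttf_summary"}: `f50`, `f10`, `f50_flag`,
#'   `f10_flag` ("ok" or ">Nyquist").
#' @export
ttf_summary <- function(ttf) {
  cross <- function(thr) {
    t <- ttf$ttf; f <- ttf$f
    below <- which(t < thr & seq_along(t) > 1L)
    below <- below[t[below - 1L] >= thr]
    if (length(below) == 0L)
      return(list(value = NA_real_, flag = ">Nyquist"))
    i <- below[1L]
    v <- f[i - 1L] + (thr - t[i - 1L]) / (t[i] - t[i - 1L]) * (f[i] - f[i - 1L])
    list(value = v, flag = "ok")
  }
  c50 <- cross(0.5); c10 <- cross(0.1)
  structure(list(f50 = c50$value, f10 = c10$value,
                 f50_flag = c50$flag, f10_flag = c10$flag),
            class = "ttf_summary")
}

#' One-call TTF of a circular insert
#'
#' Convenience wrapper: [esf_from_insert()] followed by [ttf_from_esf()].
#'
#' @inheritParams esf_from_insert
#' @inheritParams ttf_from_esf
#' @return a `ttf_result`.
#' @export
ttf_from_insert <- function(stack, insert, phantom_center = NULL,
                            bin_width_px = 0.1, r_max_mm = NULL,
                            slices = NULL, taper = TRUE, taper_frac = 0.2) {
  esf <- esf_from_insert(stack, insert, phantom_center, bin_width_px,
                         r_max_mm, slices)
  ttf_from_esf(esf, taper = taper, taper_frac = taper_frac)
}

#' Export ESF/TTF curves as CSV
#'
#' @param x an `esf_curve` or `ttf_result`.
#' @param path output path.
#' @export
export_curve <- function(x, path) {
  df <- if (inherits(x, "esf_curve"))
    data.frame(distance_mm = x$distance_mm, hu = x$value)
  else data.frame(f_per_mm = x$f, ttf = x$ttf)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
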