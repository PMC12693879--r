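# 2D noise power spectrum with second-order polynomial detrending, radial
# averaging, and the texture summaries f_peak, f_average, noise magnitude.

#' Collect square noise ROIs from a homogeneous module
#'
#' Default layout: eight square ROIs (25 mm side) per slice, centred on a
#' ring at 45-degree intervals, replicated over every slice of the stack.
#' Each (ROI, slice) pair is treated as one independent noise realisation.
#'
#' @param stack an [image_stack()] of the uniformity module.
#' @param n_per_slice ROIs per slice.
#' @param roi_mm ROI side length (mm); converted to a whole pixel count with
#'   the stack's spacing.
#' @param ring_radius_mm radius of the ROI-centre ring (mm).
#' @param phantom_center (x, y) mm; default the image centre.
#' @param slices slice indices; default all.
#' @return list of class \code{"noise_roi_set"}: `rois` (list of numeric
#'   matrices, all the same size) and `pixel_spacing`.
#' @export
extract_noise_rois <- function(stack, n_per_slice = 8L, roi_mm = 25,
                               ring_radius_mm = 50, phantom_center = NULL,
                               slices = NULL) {
  d <- dim(stack$voxels)
  dx <- stack$pixel_spacing[1L]; dy <- stack$pixel_spacing[2L]
  if (is.null(phantom_center))
    phantom_center <- c((d[2L] - 1) / 2 * dx, (d[1L] - 1) / 2 * dy)
  if (is.null(slices)) slices <- seq_len(d[3L])
  npx <- max(6L, round(roi_mm / dx))
  ang <- seq(0, 2 * pi, length.out = n_per_slice + 1L)[seq_len(n_per_slice)]
  rois <- list()
  for (k in slices) {
    sl <- stack$voxels[, , k]
    for (a in ang) {
      cx <- phantom_center[1L] + ring_radius_mm * cos(a)
      cy <- phantom_center[2L] + ring_radius_mm * sin(a)
      c0 <- round(cx / dx) + 1L - floor(npx / 2)
      r0 <- round(cy / dy) + 1L - floor(npx / 2)
      if (r0 < 1L || c0 < 1L || r0 + npx - 1L > d[1L] || c0 + npx - 1L > d[2L])
        stop("noise ROI extends outside the image")
      rois[[length(rois) + 1L]] <- sl[r0:(r0 + npx - 1L), c0:(c0 + npx - 1L)]
    }
  }
  noise_roi_set(rois, stack$pixel_spacing)
}

#' @rdname extract_noise_rois
#' @param rois list of equally sized numeric matrices.
#' @param pixel_spacing (dx, dy) mm.
#' @export
noise_roi_set <- function(rois, pixel_spacing) {
  stopifnot(length(rois) >= 1L)
  dims <- t(vapply(rois, dim, integer(2)))
  if (nrow(unique(dims)) != 1L) stop("all noise ROIs must have the same size")
  structure(list(rois = rois, pixel_spacing = as.numeric(pixel_spacing)),
            class = "noise_roi_set")
}

#' Remove a second-order polynomial trend from a pixel block
#'
#' Least-squares fit of the full bivariate polynomial of total degree <= 2
#' (terms 1, x, y, x^2, xy, y^2) in pixel coordinates, subtracted from the
#' block. This is the only low-frequency/leakage control applied before the
#' NPS Fourier transform.
#'
#' @param block numeric matrix.
#' @param return_fit if TRUE, attach the fitted surface and coefficients as
#'   attributes.
#' @return residual matrix, same size as `block`.
#' @export
detrend_roi <- function(block, return_fit = FALSE) {
  block <- as.matrix(block)
  nr <- nrow(block); nc <- ncol(block)
  if (nr < 3L || nc < 3L)
    stop("block too small to fit a second-order surface (degenerate design)")
  x <- rep((seq_len(nc) - (nc + 1) / 2), each = nr)
  y <- rep((seq_len(nr) - (nr + 1) / 2), times = nc)
  X <- cbind(1, x, y, x^2, x * y, y^2)
  fit <- stats::lm.fit(X, as.vector(block))
  resid <- matrix(fit$residuals, nr, nc)
  if (return_fit) {
    attr(resid, "fitted") <- matrix(fit$fitted.values, nr, nc)
    attr(resid, "coefficients") <- fit$coefficients
  }
  resid
}

#' 2D noise power spectrum
#'
#' \deqn{NPS_{2D}(f_x,f_y) = \frac{\Delta x \, \Delta y}{N_x N_y}
#'  \cdot \frac{1}{N_{ROI}} \sum_i |FFT_{2D}[ROI_i - FIT_i]|^2}
#' with \eqn{FIT_i} the second-order polynomial fit of each ROI and
#' \eqn{N_x, N_y} the ROI pixel dimensions (the ROI-size normalisation that
#' gives units HU^2 mm^2 and makes Parseval hold: the integral of the NPS
#' over the Nyquist square equals the detrended pixel variance). No window
#' function is applied. The returned spectrum is centred (fftshifted) with
#' ascending frequency axes.
#'
#' @param rois a [noise_roi_set()].
#' @return list of class \code{"nps_result"}: `nps2d` (matrix, fy in rows /
#'   fx in columns), `fx`, `fy` (1/mm), `pixel_spacing`, `n_roi`,
#'   `detrended_variance` (mean per-ROI residual variance).
#' @export
nps_2d <- function(rois) {
  stopifnot(inherits(rois, "noise_roi_set"))
  dx <- rois$pixel_spacing[1L]; dy <- rois$pixel_spacing[2L]
  d <- dim(rois$rois[[1L]])
  ny <- d[1L]; nx <- d[2L]
  acc <- matrix(0, ny, nx)
  v <- 0
  for (b in rois$rois) {
    r <- detrend_roi(b)
    acc <- acc + Mod(stats::fft(r))^2
    v <- v + mean(r^2)
  }
  nps <- (dx * dy / (nx * ny)) * acc / length(rois$rois)
  fx <- fft_freqs(nx, dx); fy <- fft_freqs(ny, dy)
  ox <- order(fx); oy <- order(fy)
  structure(list(nps2d = nps[oy, ox], fx = fx[ox], fy = fy[oy],
                 pixel_spacing = rois$pixel_spacing,
                 n_roi = length(rois$rois),
                 detrended_variance = v / length(rois$rois)),
            class = "nps_result")
}

#' Radial average of a 2D NPS
#'
#' Averages the 2D NPS over annular frequency bins of width equal to the
#' axial DFT bin spacing \code{1/(N dx)}. The DC cell is excluded
#' (detrending forces it to ~0 and any numerical residue would bias the
#' summaries). Bins whose centre lies beyond the inscribed Nyquist circle
#' are flagged `partial` (their annuli are truncated by the Nyquist square).
#'
#' @param nps an `nps_result` (or a plain matrix with `fx`/`fy` supplied).
#' @param fx,fy frequency axes when `nps` is a matrix.
#' @return data.frame of class \code{"nps1d"}: `f` (bin centre, 1/mm),
#'   `nps` (HU^2 mm^2), `n_cells`, `partial`.
#' @export
radial_average <- function(nps, fx = NULL, fy = NULL) {
  if (inherits(nps, "nps_result")) {
    fx <- nps$fx; fy <- nps$fy; m <- nps$nps2d
  } else m <- nps
  if (is.null(fx) || is.null(fy)) stop("frequency axes are required")
  df <- fx[2L] - fx[1L]
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  bin <- as.integer(round(rho / df))
  keep <- rho > 0                       # exclude the DC cell
  nyq <- min(max(abs(fx)), max(abs(fy)))
  agg <- tapply(m[keep], bin[keep], mean)
  cnt <- tapply(m[keep], bin[keep], length)
  f <- as.numeric(names(agg)) * df
  out <- data.frame(f = f, nps = as.numeric(agg),
                    n_cells = as.integer(cnt), partial = f > nyq)
  out <- out[order(out$f), , drop = FALSE]
  class(out) <- c("nps1d", "data.frame")
  out
}

#' NPS summary scalars
#'
#' `f_peak`: frequency of the radial NPS maximum (ties broken toward the
#' lower frequency); `f_average`: NPS-weighted mean frequency
#' \eqn{\int f \cdot NPS_{1D}(f) df / \int NPS_{1D}(f) df}; both over the
#' full annuli inside the inscribed Nyquist circle. `noise_magnitude`: the
#' square root of the integral of the 2D NPS over the whole Nyquist square
#' (Riemann sum), i.e. the stationary noise standard deviation.
#'
#' @param nps an `nps_result`.
#' @return list of class \code{"nps_summary"}: `f_peak`, `f_average`,
#'   `noise_magnitude`, `defined` (FALSE for an all-zero NPS, in which case
#'   the frequencies are NA).
#' @export
nps_summary <- function(nps) {
  stopifnot(inherits(nps, "nps_result"))
  dfx <- nps$fx[2L] - nps$fx[1L]; dfy <- nps$fy[2L] - nps$fy[1L]
  area <- sum(nps$nps2d) * dfx * dfy
  mag <- sqrt(max(area, 0))
  p <- radial_average(nps)
  p <- p[!p$partial, , drop = FALSE]
  tot <- sum(p$nps)
  if (tot <= 0) {
    return(structure(list(f_peak = NA_real_, f_average = NA_real_,
                          noise_magnitude = mag, defined = FALSE),
                     class = "nps_summary"))
  }
  f_peak <- p$f[which.max(p$nps)]       # which.max takes the first maximum
  f_avg <- sum(p$f * p$nps) / tot
  structure(list(f_peak = f_peak, f_average = f_avg, noise_magnitude = mag,
                 defined = TRUE),
            class = "nps_summary")
}

#' Export NPS results as plain text
#'
#' Writes the radial NPS as a two-column CSV (f in 1/mm, NPS in HU^2 mm^2)
#' and, optionally, the 2D NPS as a CSV matrix with the frequency axes in
#' the first row/column.
#'
#' @param nps an `nps_result`.
#' @param path_1d,path_2d output paths (`NULL` to skip).
#' @export
export_nps <- function(nps, path_1d = NULL, path_2d = NULL) {
  if (!is.null(path_1d)) {
    p <- radial_average(nps)
    utils::write.csv(p[, c("f", "nps")], path_1d, row.names = FALSE)
  }
  if (!is.null(path_2d)) {
    m <- rbind(c(NA, nps$fx), cbind(nps$fy, nps$nps2d))
    utils::write.table(m, path_2d, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(NULL)
}
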