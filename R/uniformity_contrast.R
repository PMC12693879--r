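# Uniformity index, integral non-uniformity, histogram statistics, insert CT
# numbers, Michelson contrast, CNR and SNR.

#' Uniformity index
#'
#' \deqn{UI = 100 \cdot (\bar{HU}_{periphery} - \bar{HU}_{center}) /
#'       (\bar{HU}_{center} + 1000)}
#' where the periphery value is the average of the periphery ROI means (each
#' itself averaged over the module slices upstream). A positive UI indicates
#' underestimated attenuation at the phantom centre (cupping); negative,
#' overestimation (capping).
#'
#' @param center a `roi_stats` (or single numeric mean) for the central ROI.
#' @param periphery list of `roi_stats` (or numeric vector of means) for the
#'   periphery ROIs.
#' @return UI (dimensionless, percent-like scale).
#' @export
uniformity_index <- function(center, periphery) {
  cm <- roi_mean(center)
  pm <- vapply(as_stats_list(periphery), roi_mean, numeric(1))
  if (length(pm) < 1L) stop("at least one periphery ROI is required")
  if (cm == -1000) stop("UI undefined: centre mean equals -1000 HU")
  100 * (mean(pm) - cm) / (cm + 1000)
}

roi_mean <- function(x) if (inherits(x, "roi_stats")) x$mean else as.numeric(x)

as_stats_list <- function(x) {
  if (inherits(x, "roi_stats")) list(x)
  else if (is.numeric(x)) as.list(x)
  else x
}

#' Integral non-uniformity
#'
#' \deqn{IN = (\bar{HU}_{max} - \bar{HU}_{min}) /
#'       (\bar{HU}_{max} + \bar{HU}_{min} + 2000)}
#' over the means of the centre + lateral ROIs of a homogeneous module.
#'
#' @param roi_means numeric vector of ROI mean HUs (typically 5).
#' @return IN (dimensionless).
#' @export
integral_nonuniformity <- function(roi_means) {
  roi_means <- vapply(as_stats_list(roi_means), roi_mean, numeric(1))
  if (length(roi_means) < 2L) stop("at least two ROI means are required")
  hi <- max(roi_means); lo <- min(roi_means)
  if (hi + lo == -2000) stop("IN undefined: max + min equals -2000 HU")
  (hi - lo) / (hi + lo + 2000)
}

#' Uniformity analysis of a homogeneous module
#'
#' Applies the standard layout: one central ROI plus four periphery ROIs
#' (top, right, bottom, left) at the configured periphery radius (default
#' 55 mm) and ROI diameter (default 20 mm), each averaged over the module
#' slices (default the central 13, or all slices if fewer). Returns UI, IN,
#' the per-ROI means and a cupping/capping classification following the sign
#' of UI.
#'
#' @param stack an [image_stack()] of the uniformity module.
#' @param geometry a [phantom_geometry()] supplying the layout.
#' @param phantom_center (x, y) mm of the phantom centre in image
#'   coordinates; default the image centre.
#' @return list of class \code{"uniformity_result"}: `ui`, `in_`, `roi_means`
#'   (named: center, top, right, bottom, left), `classification`.
#' @export
uniformity_analysis <- function(stack, geometry = catphan_geometry(),
                                phantom_center = NULL) {
  lay <- geometry$uniformity_layout
  d <- dim(stack$voxels)
  if (is.null(phantom_center))
    phantom_center <- c((d[2L] - 1) / 2 * stack$pixel_spacing[1L],
                        (d[1L] - 1) / 2 * stack$pixel_spacing[2L])
  ns <- min(lay$n_slices, d[3L])
  first <- floor((d[3L] - ns) / 2)
  slices <- first + seq_len(ns)
  rr <- lay$periphery_radius_mm
  centers <- list(center = c(0, 0), top = c(0, -rr), right = c(rr, 0),
                  bottom = c(0, rr), left = c(-rr, 0))
  means <- vapply(centers, function(cc) {
    roi <- roi_spec("circle", phantom_center + cc, lay$roi_diameter_mm,
                    "mm", slices)
    extract_roi(stack, roi)$mean
  }, numeric(1))
  ui <- uniformity_index(means[["center"]], means[-1L])
  inu <- integral_nonuniformity(means)
  cls <- if (ui > 0) "cupping" else if (ui < 0) "capping" else "neutral"
  structure(list(ui = ui, in_ = inu, roi_means = means,
                 classification = cls),
            class = "uniformity_result")
}

#' Histogram statistics of a pixel ROI
#'
#' Median, interquartile range (linear interpolation between order
#' statistics), skewness and excess kurtosis of the HU values of a pixel
#' block (canonically a 128 x 128 ROI in the central slice of the uniformity
#' module). Moments use the population convention. For constant input the
#' moment statistics are undefined and returned as NA with
#' `moments_defined = FALSE`; median and IQR are still returned.
#'
#' @param pixels numeric vector (or matrix) of HU values; at least 4.
#' @param bin_width histogram bin width in HU, recorded for reporting
#'   (quantiles are computed from the raw values).
#' @return list of class \code{"histogram_stats"}: `median`, `iqr`,
#'   `skewness`, `kurtosis` (excess), `bin_width`, `moments_defined`.
#' @export
histogram_stats <- function(pixels, bin_width = 1) {
  x <- as.numeric(pixels)
  if (length(x) < 4L) stop("at least 4 pixels are required")
  if (bin_width <= 0) stop("bin width must be positive")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    sk <- NA_real_; ku <- NA_real_; ok <- FALSE
  } else {
    sk <- mean((x - m)^3) / m2^1.5
    ku <- mean((x - m)^4) / m2^2 - 3
    ok <- TRUE
  }
  structure(list(median = q[2L], iqr = q[3L] - q[1L], skewness = sk,
                 kurtosis = ku, bin_width = bin_width, moments_defined = ok),
            class = "histogram_stats")
}

#' Insert CT number
#'
#' Mean and standard deviation over a circular ROI of fixed pixel diameter
#' (default 8 px) centred on a sensitometry insert. Warns when the ROI
#' diameter exceeds the insert diameter.
#'
#' @param stack an [image_stack()] of the sensitometry module.
#' @param insert an [insert_spec()] (centre relative to the phantom centre).
#' @param phantom_center (x, y) mm; default the image centre.
#' @param diameter_px ROI diameter in pixels.
#' @param slice slice index or indices.
#' @return a `roi_stats`.
#' @export
insert_hu <- function(stack, insert, phantom_center = NULL, diameter_px = 8,
                      slice = 1L) {
  d <- dim(stack$voxels)
  if (is.null(phantom_center))
    phantom_center <- c((d[2L] - 1) / 2 * stack$pixel_spacing[1L],
                        (d[1L] - 1) / 2 * stack$pixel_spacing[2L])
  roi_mm <- diameter_px * mean(stack$pixel_spacing)
  if (roi_mm > insert$diameter)
    warning("ROI diameter (", signif(roi_mm, 3),
            " mm) exceeds insert diameter for ", insert$material)
  roi <- roi_spec("circle", phantom_center + insert$center, diameter_px,
                  "px", slice)
  extract_roi(stack, roi)
}

#' Michelson contrast
#'
#' \deqn{c = (\bar{HU}_{insert} - \bar{HU}_{bkg}) /
#'       (\bar{HU}_{insert} + \bar{HU}_{bkg})}
#'
#' @param insert,bkg `roi_stats` (or numeric means).
#' @return contrast (dimensionless).
#' @export
michelson_contrast <- function(insert, bkg) {
  a <- roi_mean(insert); b <- roi_mean(bkg)
  if (a + b == 0)
    stop("Michelson contrast undefined: insert and background means sum to 0")
  (a - b) / (a + b)
}

#' Contrast-to-noise and signal-to-noise ratios
#'
#' CNR divides the Michelson contrast by the noise, estimated as the
#' standard deviation of the background ROI; SNR divides the insert ROI mean
#' by the same background standard deviation.
#'
#' @param insert,bkg `roi_stats`; `bkg$sd` must be positive.
#' @return list of class \code{"contrast_result"}: `contrast`, `noise_sd`,
#'   `cnr`, `snr`.
#' @export
cnr_snr <- function(insert, bkg) {
  if (!inherits(bkg, "roi_stats") || bkg$sd <= 0)
    stop("background ROI must have positive standard deviation")
  cc <- michelson_contrast(insert, bkg)
  structure(list(contrast = cc, noise_sd = bkg$sd,
                 cnr = cc / bkg$sd, snr = roi_mean(insert) / bkg$sd),
            class = "contrast_result")
}
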