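# Non-prewhitening detectability index for a circular task, d-prime
# protocol-comparison arithmetic, and HU-vs-mu linearity regression.

#' Circular task function
#'
#' Fourier transform of a uniform disc of diameter `diameter_mm` and
#' amplitude `contrast_hu`, evaluated on a 2D frequency grid. The analytic
#' radially symmetric form is used (first-order Bessel):
#' \deqn{W(\rho) = C \, r \, J_1(2\pi\rho r)/\rho, \qquad W(0) = C\pi r^2.}
#'
#' @param diameter_mm task diameter (mm); default the 5 mm circular task.
#' @param contrast_hu task amplitude C (HU), typically the insert-vs-
#'   background contrast.
#' @param fx,fy frequency axes (1/mm), usually the NPS grid axes.
#' @return list of class \code{"task_function"}: `w` (matrix, fy rows / fx
#'   columns), `fx`, `fy`, `diameter_mm`, `contrast_hu`.
#' @export
task_function <- function(diameter_mm = 5, contrast_hu, fx, fy) {
  stopifnot(diameter_mm > 0)
  r <- diameter_mm / 2
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  w <- matrix(contrast_hu * pi * r^2, nrow = length(fy), ncol = length(fx))
  nz <- rho > 0
  w[nz] <- contrast_hu * r * besselJ(2 * pi * rho[nz] * r, 1) / rho[nz]
  first_zero <- 3.8317 / (2 * pi * r)
  if (max(rho) < first_zero)
    warning("frequency grid ends before the first zero of the task ",
            "function; d-prime integrals will be truncated")
  structure(list(w = w, fx = fx, fy = fy, diameter_mm = diameter_mm,
                 contrast_hu = contrast_hu),
            class = "task_function")
}

# interpolate a radial TTF curve onto a 2D grid; 0 beyond the last computed
# frequency (conservative extrapolation)
ttf_on_grid <- function(ttf, rho) {
  if (is.numeric(ttf) && length(ttf) == 1L)
    return(array(ttf, dim = dim(rho)))
  if (is.function(ttf)) return(ttf(rho))
  v <- stats::approx(ttf$f, ttf$ttf, xout = pmin(rho, max(ttf$f)),
                     rule = 2)$y
  v[rho > max(ttf$f)] <- 0
  array(v, dim = dim(rho))
}

#' Non-prewhitening detectability index
#'
#' \deqn{d'^2 = \frac{\left[\iint W^2(u,v)\,TTF^2(u,v)\,du\,dv\right]^2}
#'      {\iint W^2(u,v)\,TTF^2(u,v)\,NPS(u,v)\,du\,dv}}
#' with the integrals taken as Riemann sums on the task-function grid. The
#' TTF curve is interpolated radially onto the grid (zero beyond its last
#' computed frequency); the NPS must share the grid, or may be a scalar for
#' white noise.
#'
#' @param ttf a `ttf_result`, a function of radial frequency, or the scalar
#'   1 for an ideal system.
#' @param nps an `nps_result` on the same frequency grid as `task`, or a
#'   scalar white-noise level N0 (HU^2 mm^2).
#' @param task a [task_function()].
#' @return list of class \code{"detectability_result"}: `dprime`,
#'   `numerator`, `denominator`, `infinite` (TRUE when the noise integral is
#'   zero, in which case `dprime` is Inf as a sentinel).
#' @export
detectability_index <- function(ttf, nps, task) {
  stopifnot(inherits(task, "task_function"))
  fx <- task$fx; fy <- task$fy
  du <- fx[2L] - fx[1L]; dv <- fy[2L] - fy[1L]
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  T2 <- ttf_on_grid(ttf, rho)^2
  if (inherits(nps, "nps_result")) {
    if (length(nps$fx) != length(fx) || length(nps$fy) != length(fy) ||
        max(abs(nps$fx - fx)) > 1e-9 || max(abs(nps$fy - fy)) > 1e-9)
      stop("NPS and task function are on different frequency grids")
    N <- nps$nps2d
  } else if (is.numeric(nps) && length(nps) == 1L) {
    N <- array(nps, dim = dim(rho))
  } else stop("nps must be an nps_result or a scalar white-noise level")
  wt <- task$w^2 * T2
  num <- (sum(wt) * du * dv)^2
  den <- sum(wt * N) * du * dv
  if (num == 0) {
    return(structure(list(dprime = 0, numerator = 0, denominator = den,
                          infinite = FALSE),
                     class = "detectability_result"))
  }
  if (den == 0) {
    return(structure(list(dprime = Inf, numerator = num, denominator = 0,
                          infinite = TRUE),
                     class = "detectability_result"))
  }
  structure(list(dprime = sqrt(num / den), numerator = num,
                 denominator = den, infinite = FALSE),
            class = "detectability_result")
}

#' Compare two detectability indices
#'
#' Absolute and percent relative difference between two labelled d' values.
#' The first argument is the reference (conventionally the standard /
#' larger-collimation protocol): percent = 100 (a - b) / a.
#'
#' @param a,b d' values (finite numerics or `detectability_result`s).
#' @param labels character length-2 labels.
#' @return list of class \code{"dprime_comparison"}: `labels`, `values`,
#'   `difference`, `percent` (NA with a warning when the reference is 0).
#' @export
compare_dprime <- function(a, b, labels = c("a", "b")) {
  val <- function(x) if (inherits(x, "detectability_result")) x$dprime else
    as.numeric(x)
  a <- val(a); b <- val(b)
  if (!is.finite(a) || !is.finite(b))
    stop("both d-prime values must be finite")
  pct <- if (a == 0) {
    warning("reference d-prime is 0; percent difference undefined")
    NA_real_
  } else 100 * (a - b) / a
  structure(list(labels = labels, values = c(a, b), difference = a - b,
                 percent = pct),
            class = "dprime_comparison")
}

#' HU linearity against linear attenuation coefficients
#'
#' Ordinary least squares regression HU = slope * mu + intercept over the
#' per-material (measured HU, computed mu) pairs, with the coefficient of
#' determination R^2 = 1 - SS_res / SS_tot. The attenuation coefficients mu
#' (1/cm) are supplied by the caller (spectrum modelling is out of scope).
#'
#' @param hu numeric vector of measured insert CT numbers (HU).
#' @param mu numeric vector of linear attenuation coefficients (1/cm).
#' @param materials optional material labels.
#' @return list of class \code{"linearity_result"}: `slope` (HU cm),
#'   `intercept` (HU), `r_squared`, `pairs` (data.frame).
#' @export
hu_linearity <- function(hu, mu, materials = NULL) {
  stopifnot(length(hu) == length(mu))
  if (length(hu) < 3L) stop("at least three (HU, mu) pairs are required")
  if (length(unique(mu)) == 1L)
    stop("degenerate design: all mu values identical")
  fit <- stats::lm(hu ~ mu)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((hu - mean(hu))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  pairs <- data.frame(material = if (is.null(materials))
    paste0("m", seq_along(hu)) else materials, hu = hu, mu = mu)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, pairs = pairs),
            class = "linearity_result")
}

#' Bundled reference d-prime table
#'
#' Published reference d' values measured on a clinical photon-counting CT
#' scanner with a Catphan600 phantom (protocol x material, 5 mm circular
#' task, NPW observer). Used by the protocol-comparison arithmetic; these
#' are inputs, not outputs of this package.
#'
#' @return data.frame with columns `protocol`, `parameters` and one column
#'   per material.
#' @export
dprime_reference <- function() {
  path <- system.file("extdata", "dprime_reference.csv", package = "ctiq")
  utils::read.csv(path, check.names = FALSE)
}
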