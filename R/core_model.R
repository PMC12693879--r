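# ---- domain types -----------------------------------------------------------

#' Calibrated CT image stack
#'
#' Container for an axial CT slice stack already rescaled to Hounsfield units
#' (HU), together with its physical sampling. Voxels are stored as a 3D array
#' indexed \code{[row(y), col(x), slice(z)]}. Physical in-plane coordinates are
#' measured in mm from the centre of the top-left pixel: pixel \code{(r, c)}
#' (1-based indices) sits at \code{x = (c-1)*dx}, \code{y = (r-1)*dy}.
#'
#' @param voxels 3D numeric array of CT numbers in HU.
#' @param pixel_spacing numeric length-2, (dx, dy) in mm; both > 0.
#' @param z_positions numeric, one axial position (mm) per slice, strictly
#'   monotonic.
#' @param slice_thickness_nominal nominal reconstructed slice thickness (mm),
#'   informational.
#' @param meta a [protocol_meta()] descriptor. Purely descriptive: no metric
#'   computation reads kV/mAs/CTDIvol.
#' @return An object of class \code{"image_stack"}.
#' @export
image_stack <- function(voxels, pixel_spacing, z_positions,
                        slice_thickness_nominal = NA_real_,
                        meta = protocol_meta()) {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3L, length(pixel_spacing) == 2L)
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be positive")
  if (length(z_positions) != dim(voxels)[3L])
    stop("z_positions length must equal the number of slices")
  if (length(z_positions) > 1L) {
    dz <- diff(z_positions)
    if (!(all(dz > 0) || all(dz < 0)))
      stop("z_positions must be strictly monotonic")
  }
  structure(list(voxels = voxels,
                 pixel_spacing = as.numeric(pixel_spacing),
                 z_positions = as.numeric(z_positions),
                 slice_thickness_nominal = slice_thickness_nominal,
                 meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d slice(s), spacing %.4g x %.4g mm\n",
              d[2L], d[1L], d[3L], x$pixel_spacing[1L], x$pixel_spacing[2L]))
  invisible(x)
}

#' Acquisition-protocol metadata
#'
#' Descriptive acquisition metadata (protocol label, kV, mAs, collimation,
#' reconstruction kernel, CTDIvol). Carried along for reporting only; by
#' contract no image-quality metric in this package reads these fields
#' numerically.
#'
#' @param protocol_id label such as "H", "TA4 UHR".
#' @param kv tube potential (kV).
#' @param mas tube load (mAs).
#' @param collimation collimation label, e.g. "144 x 0.4".
#' @param recon_kernel reconstruction kernel label, e.g. "Br40 Q4".
#' @param ctdi_vol volume CT dose index (mGy), informational only.
#' @return list of class \code{"protocol_meta"}.
#' @export
protocol_meta <- function(protocol_id = NA_character_, kv = NA_real_,
                          mas = NA_real_, collimation = NA_character_,
                          recon_kernel = NA_character_, ctdi_vol = NA_real_) {
  structure(list(protocol_id = protocol_id, kv = kv, mas = mas,
                 collimation = collimation, recon_kernel = recon_kernel,
                 ctdi_vol = ctdi_vol),
            class = "protocol_meta")
}

#' Circular insert specification
#'
#' @param material material name (e.g. "Teflon").
#' @param center numeric (x, y) in mm relative to the phantom centre.
#' @param diameter insert diameter in mm; > 0.
#' @param nominal_hu nominal CT number of the material (HU).
#' @return list of class \code{"insert_spec"}.
#' @export
insert_spec <- function(material, center, diameter, nominal_hu) {
  stopifnot(diameter > 0, length(center) == 2L)
  structure(list(material = material, center = as.numeric(center),
                 diameter = diameter, nominal_hu = nominal_hu),
            class = "insert_spec")
}

#' Tilted wire-ramp specification
#'
#' A wire ramp crossing the slice plane at a tilt angle; in-plane it appears
#' as a bright segment along \code{direction} whose extent encodes the slice
#' sensitivity profile width.
#'
#' @param center (x, y) mm relative to the phantom centre.
#' @param direction in-plane unit vector along the ramp (normalised here).
#' @param tilt_deg tilt angle in degrees, in (0, 90); default 23.
#' @return list of class \code{"ramp_spec"}.
#' @export
ramp_spec <- function(center, direction, tilt_deg = 23) {
  stopifnot(length(center) == 2L, length(direction) == 2L)
  if (tilt_deg <= 0 || tilt_deg >= 90) stop("tilt angle must be in (0, 90) degrees")
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("direction must be non-zero")
  structure(list(center = as.numeric(center),
                 direction = as.numeric(direction) / n,
                 tilt_deg = tilt_deg),
            class = "ramp_spec")
}

#' Phantom geometry configuration
#'
#' Layout of the QA phantom modules: insert positions, wire ramps, module
#' z-ranges and the uniformity ROI layout. Geometry is supplied explicitly
#' (matching laser-aligned phantom positioning); it is never auto-detected,
#' though [locate_center()] can refine the phantom centre.
#'
#' @param phantom_radius phantom disc radius in mm.
#' @param background_hu CT number of the phantom body material.
#' @param inserts list of [insert_spec()] objects.
#' @param ramps list of [ramp_spec()] objects.
#' @param module_z named list mapping module id ("ctp404", "ctp486",
#'   "ctp515") to a c(zmin, zmax) range in mm.
#' @param uniformity_layout list with \code{periphery_radius_mm} (default 55),
#'   \code{roi_diameter_mm} (default 20) and \code{n_slices} (default 13): one
#'   centre ROI plus four periphery ROIs (top/right/bottom/left) averaged over
#'   the module slices.
#' @return list of class \code{"phantom_geometry"}.
#' @export
phantom_geometry <- function(phantom_radius = 100, background_hu = 90,
                             inserts = list(), ramps = list(),
                             module_z = list(),
                             uniformity_layout = list(periphery_radius_mm = 55,
                                                      roi_diameter_mm = 20,
                                                      n_slices = 13)) {
  for (ins in inserts) {
    r <- sqrt(sum(ins$center^2)) + ins$diameter / 2
    if (r > phantom_radius)
      stop("insert '", ins$material, "' lies outside the phantom radius")
  }
  structure(list(phantom_radius = phantom_radius,
                 background_hu = background_hu,
                 inserts = inserts, ramps = ramps, module_z = module_z,
                 uniformity_layout = uniformity_layout),
            class = "phantom_geometry")
}

#' Default Catphan600-style geometry
#'
#' Sensitometry module with seven material inserts (air, PMP, LDPE,
#' Polystyrene, acrylic, Delrin, Teflon) of 12.2 mm diameter on a 58.4 mm
#' radius circle, four 23-degree tilted wire ramps near the centre, a
#' homogeneous uniformity module and a low-contrast module. Nominal CT
#' numbers are the mid-range manufacturer values for the materials.
#'
#' @param pixel_note unused; reserved.
#' @return a [phantom_geometry()] object.
#' @export
catphan_geometry <- function(pixel_note = NULL) {
  r_ins <- 58.4
  ang <- function(a) c(cos(a * pi / 180), sin(a * pi / 180)) * r_ins
  inserts <- list(
    insert_spec("air",         ang(90),  12.2, -1000),
    insert_spec("PMP",         ang(150), 12.2, -200),
    insert_spec("LDPE",        ang(210), 12.2, -100),
    insert_spec("Polystyrene", ang(270), 12.2, -35),
    insert_spec("acrylic",     ang(330), 12.2, 120),
    insert_spec("Delrin",      ang(30),  12.2, 340),
    insert_spec("Teflon",      ang(0),   12.2, 990)
  )
  ramps <- list(
    ramp_spec(c(0,  25), c(1, 0)),
    ramp_spec(c(0, -25), c(1, 0)),
    ramp_spec(c( 25, 0), c(0, 1)),
    ramp_spec(c(-25, 0), c(0, 1))
  )
  phantom_geometry(
    phantom_radius = 100, background_hu = 90,
    inserts = inserts, ramps = ramps,
    module_z = list(ctp404 = c(0, 20), ctp486 = c(40, 60), ctp515 = c(80, 100))
  )
}

#' Read / write a phantom geometry as a JSON config
#'
#' Serialises the module layout (inserts, ramps, uniformity ROI layout,
#' module z-ranges) to a structured text file, and reads it back.
#'
#' @param path file path.
#' @param geometry a [phantom_geometry()].
#' @return `read_geometry` returns a [phantom_geometry()].
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  inserts <- lapply(seq_len(NROW(g$inserts)), function(i)
    insert_spec(g$inserts$material[i],
                c(g$inserts$x[i], g$inserts$y[i]),
                g$inserts$diameter[i], g$inserts$nominal_hu[i]))
  ramps <- lapply(seq_len(NROW(g$ramps)), function(i)
    ramp_spec(c(g$ramps$x[i], g$ramps$y[i]),
              c(g$ramps$dir_x[i], g$ramps$dir_y[i]), g$ramps$tilt_deg[i]))
  phantom_geometry(phantom_radius = g$phantom_radius,
                   background_hu = g$background_hu,
                   inserts = inserts, ramps = ramps,
                   module_z = g$module_z,
                   uniformity_layout = g$uniformity_layout)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  ins <- do.call(rbind, lapply(geometry$inserts, function(i)
    data.frame(material = i$material, x = i$center[1], y = i$center[2],
               diameter = i$diameter, nominal_hu = i$nominal_hu)))
  rmp <- do.call(rbind, lapply(geometry$ramps, function(r)
    data.frame(x = r$center[1], y = r$center[2], dir_x = r$direction[1],
               dir_y = r$direction[2], tilt_deg = r$tilt_deg)))
  jsonlite::write_json(list(phantom_radius = geometry$phantom_radius,
                            background_hu = geometry$background_hu,
                            inserts = ins, ramps = rmp,
                            module_z = geometry$module_z,
                            uniformity_layout = geometry$uniformity_layout),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Region-of-interest specification
#'
#' @param shape "circle" or "square".
#' @param center (x, y) position in mm (image coordinates, from the top-left
#'   pixel centre).
#' @param size diameter (circle) or side length (square).
#' @param size_unit "mm" (converted with the stack's own pixel spacing) or
#'   "px" (used verbatim, e.g. the 8-pixel insert ROI).
#' @param slice slice index (1-based). May be a vector to pool slices.
#' @return list of class \code{"roi_spec"}.
#' @export
roi_spec <- function(shape = c("circle", "square"), center, size,
                     size_unit = c("mm", "px"), slice = 1L) {
  shape <- match.arg(shape)
  size_unit <- match.arg(size_unit)
  stopifnot(length(center) == 2L, size > 0)
  structure(list(shape = shape, center = as.numeric(center), size = size,
                 size_unit = size_unit, slice = as.integer(slice)),
            class = "roi_spec")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# logical mask of pixels whose centres fall inside the ROI on one slice
roi_mask <- function(stack, roi) {
  d <- dim(stack$voxels)
  dx <- stack$pixel_spacing[1L]; dy <- stack$pixel_spacing[2L]
  xs <- (seq_len(d[2L]) - 1) * dx
  ys <- (seq_len(d[1L]) - 1) * dy
  cx <- roi$center[1L]; cy <- roi$center[2L]
  if (roi$size_unit == "px") {
    sx <- roi$size * dx; sy <- roi$size * dy
  } else {
    sx <- roi$size; sy <- roi$size
  }
  if (roi$shape == "circle") {
    # circular ROIs assume (near-)isotropic sampling; radius from the mean spacing
    r2 <- (if (roi$size_unit == "px") roi$size * (dx + dy) / 2 else roi$size)^2 / 4
    outer(ys, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r2)
  } else {
    outer(ys, xs, function(y, x) abs(x - cx) <= sx / 2 & abs(y - cy) <= sy / 2)
  }
}

#' Extract ROI statistics
#'
#' Mean and standard deviation of the CT numbers whose pixel centres fall
#' inside the ROI shape. The standard deviation is the population form
#' (divide by N) throughout the package, so CNR/SNR/NPS normalisations are
#' mutually consistent.
#'
#' @param stack an [image_stack()].
#' @param roi a [roi_spec()]. If `roi$slice` has several indices the pixels of
#'   all those slices are pooled.
#' @param return_pixels if TRUE, attach the raw pixel values as
#'   \code{attr(, "pixels")} (and the single-slice mask as \code{attr(, "mask")}).
#' @return list of class \code{"roi_stats"} with fields `mean`, `sd`, `n`.
#' @export
extract_roi <- function(stack, roi, return_pixels = FALSE) {
  d <- dim(stack$voxels)
  if (any(roi$slice < 1L) || any(roi$slice > d[3L]))
    stop("ROI slice index out of range")
  dx <- stack$pixel_spacing[1L]; dy <- stack$pixel_spacing[2L]
  half <- if (roi$size_unit == "px") roi$size * max(dx, dy) / 2 else roi$size / 2
  xmax <- (d[2L] - 1) * dx; ymax <- (d[1L] - 1) * dy
  if (roi$center[1L] - half < -dx / 2 || roi$center[1L] + half > xmax + dx / 2 ||
      roi$center[2L] - half < -dy / 2 || roi$center[2L] + half > ymax + dy / 2)
    stop("ROI extends outside the image bounds")
  m <- roi_mask(stack, roi)
  if (!any(m)) stop("ROI selects zero pixels")
  px <- unlist(lapply(roi$slice, function(k) stack$voxels[, , k][m]),
               use.names = FALSE)
  out <- structure(list(mean = mean(px), sd = pop_sd(px), n = length(px)),
                   class = "roi_stats")
  if (return_pixels) {
    attr(out, "pixels") <- px
    attr(out, "mask") <- m
  }
  out
}

#' Locate the phantom centre on a slice
#'
#' Centroid of the thresholded foreground of a slice showing one bright
#' phantom disc on a dark (air) background. Used only as an optional
#' refinement when the configuration does not pin the centre.
#'
#' @param stack an [image_stack()].
#' @param slice slice index.
#' @param threshold HU threshold; default is the midpoint of the slice's
#'   range.
#' @return numeric (x, y) in mm.
#' @export
locate_center <- function(stack, slice = 1L, threshold = NULL) {
  sl <- stack$voxels[, , slice]
  if (is.null(threshold)) threshold <- (max(sl) + min(sl)) / 2
  m <- sl > threshold
  if (!any(m)) stop("no foreground above threshold; cannot locate phantom")
  idx <- which(m, arr.ind = TRUE)
  c(x = (mean(idx[, 2L]) - 1) * stack$pixel_spacing[1L],
    y = (mean(idx[, 1L]) - 1) * stack$pixel_spacing[2L])
}

# ---- plain-text series i/o --------------------------------------------------

#' Read a slice series from plain-text slice files
#'
#' Each slice file carries a one-line JSON header (pixel spacing, z position,
#' rescale slope/intercept, dimensions, optional protocol metadata) followed
#' by the stored pixel matrix, one image row per line. Stored values are
#' rescaled to HU at read time (\code{HU = slope * stored + intercept}) and
#' slices are sorted by ascending z.
#'
#' @param paths character vector of slice-file paths forming one series.
#' @return an [image_stack()] in HU.
#' @export
load_series <- function(paths) {
  if (length(paths) < 1L) stop("no slice files given")
  slices <- lapply(paths, read_slice_file)
  sp <- t(vapply(slices, function(s) s$pixel_spacing, numeric(2)))
  if (nrow(unique(round(sp, 10))) != 1L)
    stop("inconsistent pixel spacing across series")
  dims <- t(vapply(slices, function(s) dim(s$hu), integer(2)))
  if (nrow(unique(dims)) != 1L) stop("inconsistent slice dimensions")
  z <- vapply(slices, function(s) s$z, numeric(1))
  if (anyDuplicated(z)) stop("duplicated z positions in series")
  ord <- order(z)
  vox <- array(NA_real_, c(dims[1L, 1L], dims[1L, 2L], length(slices)))
  for (i in seq_along(ord)) vox[, , i] <- slices[[ord[i]]]$hu
  meta <- slices[[ord[1L]]]$meta
  image_stack(vox, slices[[1L]]$pixel_spacing, z[ord],
              slice_thickness_nominal = slices[[1L]]$slice_thickness,
              meta = meta)
}

read_slice_file <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (is.null(hdr$pixel_spacing))
    stop("missing pixel spacing in slice header: ", path)
  if (is.null(hdr$z)) stop("missing z position in slice header: ", path)
  slope <- if (is.null(hdr$rescale_slope)) 1 else hdr$rescale_slope
  inter <- if (is.null(hdr$rescale_intercept)) 0 else hdr$rescale_intercept
  vals <- scan(con, what = numeric(), n = hdr$nrow * hdr$ncol, quiet = TRUE)
  stored <- matrix(vals, nrow = hdr$nrow, ncol = hdr$ncol, byrow = TRUE)
  meta <- if (is.null(hdr$meta)) protocol_meta() else
    do.call(protocol_meta, hdr$meta[!vapply(hdr$meta, is.null, logical(1))])
  list(hu = slope * stored + inter,
       pixel_spacing = as.numeric(hdr$pixel_spacing), z = hdr$z,
       slice_thickness = if (is.null(hdr$slice_thickness)) NA_real_ else
         hdr$slice_thickness,
       meta = meta)
}

#' Write an image stack as plain-text slice files
#'
#' Inverse of [load_series()]: one text file per slice with a JSON header
#' line followed by the stored pixel matrix. Stored values are
#' \code{(HU - intercept) / slope}; with the defaults (slope 1, intercept
#' -1024) integer HU round-trip exactly.
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @param rescale_slope,rescale_intercept rescale tags written to each header.
#' @param digits significant digits for stored values.
#' @return character vector of written file paths, in z order.
#' @export
write_series <- function(stack, dir, rescale_slope = 1,
                         rescale_intercept = -1024, digits = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$voxels)
  paths <- character(d[3L])
  for (k in seq_len(d[3L])) {
    hdr <- list(pixel_spacing = stack$pixel_spacing,
                z = stack$z_positions[k],
                rescale_slope = rescale_slope,
                rescale_intercept = rescale_intercept,
                nrow = d[1L], ncol = d[2L],
                slice_thickness = stack$slice_thickness_nominal,
                meta = unclass(stack$meta))
    stored <- (stack$voxels[, , k] - rescale_intercept) / rescale_slope
    p <- file.path(dir, sprintf("slice_%03d.txt", k))
    con <- file(p, "w")
    writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
    write.table(format(stored, digits = digits, trim = TRUE,
                       scientific = FALSE),
                con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
    paths[k] <- p
  }
  paths
}
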