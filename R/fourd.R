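#' Excitation-operator spectrum from an unaligned calibration image
#'
#' A calibration sample contains the structure of interest with no intrinsic
#' alignment, so the second-order angular moments of its Fourier magnitude
#' reflect only the excitation polarisation of the system. This is the
#' single-image spectrum path ([anisotropy_single()] followed by
#' [anisotropy_spectrum()]); it presumes a large number of randomly oriented
#' fibres in the frame.
#'
#' @param calibration_img numeric matrix, at least 64 x 64.
#' @param r_min,r_max ring range as in [anisotropy_spectrum()].
#' @return `anisotropy_spectrum` in single mode.
#' @export
calibration_spectrum <- function(calibration_img, r_min = 1, r_max = NULL) {
  calibration_img <- as.matrix(calibration_img)
  if (min(dim(calibration_img)) < 64)
    stop("calibration image must be at least 64x64 (too few rings otherwise)")
  anisotropy_spectrum(anisotropy_single(calibration_img), r_min, r_max)
}

#' Average anisotropy spectra across calibration fields
#'
#' Per-ring moment estimates of a single field fluctuate with the speckle
#' of its Fourier magnitudes, so a calibration session typically images
#' several fields of view and averages their spectra before building the
#' inverse operator (noise shrinks with the square root of the number of
#' fields). All spectra must share mode, ring range and source shape.
#'
#' @param specs list of `anisotropy_spectrum` objects.
#' @return an `anisotropy_spectrum` with per-ring mean moments.
#' @export
mean_spectrum <- function(specs) {
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "anisotropy_spectrum")))
  ref <- specs[[1]]
  for (s in specs[-1])
    if (!identical(s$frequencies, ref$frequencies) ||
        !identical(s$mode, ref$mode))
      stop("spectra must share ring range and mode")
  ref$gamma_c <- rowMeans(vapply(specs, `[[`, ref$gamma_c, "gamma_c"))
  ref$gamma_s <- rowMeans(vapply(specs, `[[`, ref$gamma_s, "gamma_s"))
  ref
}

#' Moving-average smoothing of an anisotropy spectrum
#'
#' Applies a centred n-point moving average independently to the gamma_c
#' and gamma_s traces; windows shrink at the spectrum ends. Useful before
#' operator construction when calibration spectra are noisy; `n_points = 1`
#' is the identity.
#'
#' @param spec an `anisotropy_spectrum`.
#' @param n_points odd window size (>= 1).
#' @return smoothed `anisotropy_spectrum`.
#' @export
smooth_spectrum <- function(spec, n_points) {
  stopifnot(inherits(spec, "anisotropy_spectrum"))
  if (n_points < 1 || n_points %% 2 == 0)
    stop("n_points must be an odd integer >= 1")
  if (n_points == 1) return(spec)
  h <- (n_points - 1) / 2
  k <- length(spec$frequencies)
  avg <- function(v) vapply(seq_len(k), function(i) {
    w <- max(1, i - h):min(k, i + h)
    mean(v[w])
  }, numeric(1))
  spec$gamma_c <- avg(spec$gamma_c)
  spec$gamma_s <- avg(spec$gamma_s)
  spec
}

#' Build the inverse excitation operator from a calibration spectrum
#'
#' Reconstructs, for every Fourier coefficient at ring r and angle theta,
#' the modelled excitation ring profile from the measured moments and takes
#' its reciprocal:
#' `value = 1 / max(1 + 2*gamma_c(r)*cos(2*theta) + 2*gamma_s(r)*sin(2*theta),
#' clamp_floor)`.
#' The factor 2 converts the measured moments back to profile amplitudes
#' (the second-order moment of `1 + A*cos(2*theta)` is `A/2` by
#' orthogonality), so multiplying the operator by the bias profile it was
#' estimated from cancels to 1. Rings below `start_radius`, and DC, are left
#' at exactly 1 ("leave the lowest frequencies unmodified"), which also
#' suppresses tile-seam artefacts in patch-wise use. Each coefficient gets
#' its exact continuous (r, theta); r is then rounded to the nearest
#' measured ring, and rings beyond the measured range reuse the last
#' available moment pair.
#'
#' @param spec calibration `anisotropy_spectrum`.
#' @param shape integer length-2, (rows, cols) of the transform the operator
#'   will multiply.
#' @param start_radius lowest ring modified (default 2).
#' @param clamp_floor minimum allowed denominator (default 0.05); a warning
#'   is raised if the reconstructed profile actually hits it.
#' @return object of class `correction_operator` with fields `values`
#'   (positive m x n matrix in *uncentred* layout, ready for a direct
#'   product with an uncentred transform), `start_radius`, `clamp_floor`
#'   and `source_spectrum`.
#' @export
inverse_operator <- function(spec, shape, start_radius = 2,
                             clamp_floor = 0.05) {
  stopifnot(inherits(spec, "anisotropy_spectrum"),
            length(shape) == 2, start_radius >= 1, clamp_floor > 0)
  m <- as.integer(shape[1]); n <- as.integer(shape[2])
  g <- freq_grids(m, n)
  ring <- round(g$r)
  idx <- pmin(pmax(ring, min(spec$frequencies)), max(spec$frequencies)) -
    min(spec$frequencies) + 1
  gc <- spec$gamma_c[idx]
  gs <- spec$gamma_s[idx]
  denom <- 1 + 2 * gc * g$cos2t + 2 * gs * g$sin2t
  active <- ring >= start_radius
  if (any(denom[active] < clamp_floor))
    warning("reconstructed excitation profile clamped at floor ",
            clamp_floor, " (large measured moments)")
  values <- matrix(1, m, n)
  values[active] <- 1 / pmax(denom[active], clamp_floor)
  structure(list(values = ifftshift2(values), start_radius = start_radius,
                 clamp_floor = clamp_floor, source_spectrum = spec),
            class = "correction_operator")
}

#' @export
print.correction_operator <- function(x, ...) {
  cat(sprintf(
    "<correction_operator> %dx%d, start radius %d, clamp floor %g\n",
    nrow(x$values), ncol(x$values), x$start_radius, x$clamp_floor))
  cat(sprintf("  multiplier range [%.4f, %.4f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Apply a correction operator to an image
#'
#' Multiplies the image's Fourier transform element-wise by the (real,
#' positive) inverse operator and inverse-transforms. Only coefficient
#' amplitudes change: phase - the position/structure content of the image -
#' is preserved exactly, and relative brightness across orientations is
#' rebalanced.
#'
#' @param img numeric matrix.
#' @param op a [inverse_operator()] result of matching shape.
#' @return corrected numeric matrix (float, unclipped).
#' @export
correct_image <- function(img, op) {
  stopifnot(inherits(op, "correction_operator"))
  img <- as.matrix(img)
  if (!all(dim(img) == dim(op$values)))
    stop("image and operator shapes differ")
  y <- stats::fft(img) * op$values
  Re(stats::fft(y, inverse = TRUE)) / length(y)
}

# tile boundary starts/ends: equal floor-sized tiles, remainder absorbed by
# the last row/column of tiles so the tiling covers the image exactly
tile_bounds <- function(extent, k) {
  size <- extent %/% k
  start <- (seq_len(k) - 1) * size + 1
  end <- c(start[-1] - 1, extent)
  cbind(start, end)
}

#' Patch-wise depolarisation correction
#'
#' For spatially varying illumination polarisation, the image and its
#' calibration are tiled (e.g. 7 x 7), and the full calibration -> inverse
#' operator -> correction chain runs independently per tile before
#' reassembly. Tiles must be small enough that the polarisation is nearly
#' constant within each one but large enough to hold a representative
#' spread of fibre orientations. Low-frequency discontinuities between
#' neighbouring tiles are suppressed by leaving rings below `start_radius`
#' untouched; raising `start_radius` (with mild spectrum smoothing) removes
#' residual seam artefacts without affecting downstream alignment analysis.
#'
#' @param img image to correct.
#' @param calibration_img unaligned calibration image, same dimensions.
#' @param n_rows,n_cols tiling counts (default 7 x 7). Use 1 x 1 for a
#'   whole-frame correction.
#' @param start_radius lowest corrected ring per tile (default 2).
#' @param smoothing odd moving-average window for the per-tile spectra
#'   (default 1 = none).
#' @param clamp_floor denominator floor as in [inverse_operator()].
#' @return corrected numeric matrix.
#' @export
patchwise_correct <- function(img, calibration_img, n_rows = 7, n_cols = 7,
                              start_radius = 2, smoothing = 1,
                              clamp_floor = 0.05) {
  img <- as.matrix(img); calibration_img <- as.matrix(calibration_img)
  if (!all(dim(img) == dim(calibration_img)))
    stop("image and calibration image must share dimensions")
  rb <- tile_bounds(nrow(img), n_rows)
  cb <- tile_bounds(ncol(img), n_cols)
  if (min(rb[, 2] - rb[, 1], cb[, 2] - cb[, 1]) + 1 < 64)
    stop("tiles smaller than 64 px; reduce the tiling counts")
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      rr <- rb[i, 1]:rb[i, 2]
      cc <- cb[j, 1]:cb[j, 2]
      spec <- calibration_spectrum(calibration_img[rr, cc])
      spec <- smooth_spectrum(spec, smoothing)
      op <- inverse_operator(spec, c(length(rr), length(cc)),
                             start_radius = start_radius,
                             clamp_floor = clamp_floor)
      out[rr, cc] <- correct_image(img[rr, cc], op)
    }
  }
  out
}

#' Polarisation axis implied by a calibration spectrum
#'
#' Converts the measured moments at structure-bearing rings into the
#' real-space polarisation angle: the Fourier ring profile peaks
#' perpendicular to the favoured fibre orientation, so the implied axis is
#' `0.5*atan2(gamma_s, gamma_c) - 90` degrees (mod 180), weighted across
#' the requested rings by moment magnitude.
#'
#' @param spec an `anisotropy_spectrum`.
#' @param rings optional subset of ring indices to use (default: all).
#' @return angle in degrees in \[0, 180).
#' @export
implied_polarisation_angle <- function(spec, rings = NULL) {
  stopifnot(inherits(spec, "anisotropy_spectrum"))
  keep <- if (is.null(rings)) rep(TRUE, length(spec$frequencies))
  else spec$frequencies %in% rings
  z <- sum(complex(real = spec$gamma_c[keep],
                   imaginary = spec$gamma_s[keep]))
  ((Arg(z) / 2) * 180 / pi - 90) %% 180
}

#' Forward excitation-polarisation operator
#'
#' Constructs the frequency-space excitation operator of the method's image
#' model: a real multiplier `1 + strength*cos(2*(theta - (angle_deg + 90)))`
#' at every ring `r >= start_radius` (the +90 places the Fourier-space peak
#' perpendicular to the favoured real-space fibre orientation). Applying it
#' with [correct_image()] imposes a known, exactly model-conformant
#' polarisation bias on an image - the forward counterpart of
#' [inverse_operator()], useful for simulation studies of the correction.
#'
#' @param angle_deg favoured real-space fibre orientation (the polarisation
#'   axis), degrees.
#' @param strength modulation amplitude in \[0, 1).
#' @param shape (rows, cols) of the target transform.
#' @param start_radius lowest ring modified (default 1: all but DC).
#' @return a `correction_operator` (positive multiplier, uncentred layout).
#' @export
excitation_operator <- function(angle_deg, strength, shape,
                                start_radius = 1) {
  stopifnot(strength >= 0, strength < 1, length(shape) == 2)
  m <- as.integer(shape[1]); n <- as.integer(shape[2])
  g <- freq_grids(m, n)
  th0 <- (angle_deg + 90) * pi / 180
  values <- 1 + strength * (g$cos2t * cos(2 * th0) + g$sin2t * sin(2 * th0))
  values[round(g$r) < start_radius] <- 1
  structure(list(values = ifftshift2(values), start_radius = start_radius,
                 clamp_floor = NA_real_, source_spectrum = NULL),
            class = "correction_operator")
}
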