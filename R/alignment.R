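#' Fibre orientation and eccentricity of one image patch
#'
#' The centred power spectrum of the (mean-subtracted) patch, restricted to
#' the inscribed disc, is treated as a 2-D distribution: its central
#' moments mu20, mu02, mu11 define an equivalent ellipse whose roots
#' `a, b = (mu20 + mu02)/2 +/- sqrt(4*mu11^2 + (mu20 - mu02)^2)/2`
#' give the eccentricity `e = sqrt(1 - b^2/a^2)` (0 = isotropic patch, 1 =
#' perfectly aligned fibres). Subtracting the patch mean removes the DC
#' spike (which otherwise dominates the moments), and the disc removes the
#' corner regions of the square spectral support, whose radial reach would
#' dilute the angular signal. The reported angle is the semimajor-axis
#' orientation rotated back into the real-space fibre frame (Fourier
#' structure lies perpendicular to the fibres).
#'
#' @param patch square numeric matrix, side >= 32.
#' @return object of class `eccentricity_result`: list with `eccentricity`,
#'   `angle_deg` (degrees in \[0, 180), `NA` if undefined), `a`, `b`.
#' @export
patch_orientation <- function(patch) {
  patch <- as.matrix(patch)
  if (nrow(patch) != ncol(patch)) stop("patch must be square")
  if (nrow(patch) < 32) stop("patch side must be at least 32 px")
  w <- fftshift2(Mod(stats::fft(patch - mean(patch)))^2)
  np <- nrow(patch)
  ctr <- floor(np / 2) + 1
  d2 <- outer((seq_len(np) - ctr)^2, (seq_len(np) - ctr)^2, "+")
  w[d2 > (np / 2 - 1)^2] <- 0
  s <- sum(w)
  if (s <= 0)
    return(structure(list(eccentricity = 0, angle_deg = NA_real_,
                          a = 0, b = 0), class = "eccentricity_result"))
  w <- w / s
  x <- matrix(seq_len(ncol(w)), nrow(w), ncol(w), byrow = TRUE)  # columns
  y <- matrix(seq_len(nrow(w)), nrow(w), ncol(w))                # rows
  xb <- sum(w * x); yb <- sum(w * y)
  mu20 <- sum(w * (x - xb)^2)
  mu02 <- sum(w * (y - yb)^2)
  mu11 <- sum(w * (x - xb) * (y - yb))
  half_span <- sqrt(4 * mu11^2 + (mu20 - mu02)^2) / 2
  a <- (mu20 + mu02) / 2 + half_span
  b <- (mu20 + mu02) / 2 - half_span
  b <- min(max(b, 0), a)   # guard FP: b in [0, a] before the ratio
  e <- if (a > 0) sqrt(1 - (b / a)^2) else 0
  # semimajor-axis angle in the row-down image frame, then flip to the
  # anticlockwise maths frame and rotate 90 deg into the fibre frame
  phi_img <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  angle <- (-phi_img + 90) %% 180
  structure(list(eccentricity = e, angle_deg = angle, a = a, b = b),
            class = "eccentricity_result")
}

#' @export
print.eccentricity_result <- function(x, ...) {
  cat(sprintf("<eccentricity_result> e = %.3f, angle = %s deg\n",
              x$eccentricity,
              if (is.na(x$angle_deg)) "NA" else sprintf("%.1f", x$angle_deg)))
  invisible(x)
}

#' Sliding-window angle and eccentricity maps
#'
#' Applies [patch_orientation()] over square windows tiled across the image
#' with the given overlap (AFT-style local analysis; the reference settings
#' are 250-pixel windows with 50% overlap). Only complete windows are
#' analysed; no masking or thresholding is applied.
#'
#' @param img numeric matrix larger than one window.
#' @param window_px window side in pixels (default 250).
#' @param overlap fractional overlap between neighbouring windows in
#'   \[0, 1) (default 0.5).
#' @return object of class `alignment_maps`: list with matrices `angle_map`
#'   (degrees) and `eccentricity_map`, plus `window_px`, `overlap`,
#'   `window_rows`, `window_cols` (top-left pixel of each window).
#' @export
alignment_maps <- function(img, window_px = 250, overlap = 0.5) {
  img <- as.matrix(img)
  if (window_px > min(dim(img)))
    stop("window larger than image")
  stopifnot(overlap >= 0, overlap < 1)
  stride <- max(1L, round(window_px * (1 - overlap)))
  rs <- seq(1L, nrow(img) - window_px + 1L, by = stride)
  cs <- seq(1L, ncol(img) - window_px + 1L, by = stride)
  ang <- ecc <- matrix(NA_real_, length(rs), length(cs))
  for (i in seq_along(rs)) {
    for (j in seq_along(cs)) {
      res <- patch_orientation(img[rs[i]:(rs[i] + window_px - 1L),
                                   cs[j]:(cs[j] + window_px - 1L)])
      ang[i, j] <- res$angle_deg
      ecc[i, j] <- res$eccentricity
    }
  }
  structure(list(angle_map = ang, eccentricity_map = ecc,
                 window_px = window_px, overlap = overlap,
                 window_rows = rs, window_cols = cs),
            class = "alignment_maps")
}

#' @export
print.alignment_maps <- function(x, ...) {
  a <- x$angle_map[!is.na(x$angle_map)]
  cat(sprintf(
    "<alignment_maps> %dx%d windows of %d px (overlap %.0f%%)\n",
    nrow(x$angle_map), ncol(x$angle_map), x$window_px, 100 * x$overlap))
  if (length(a))
    cat(sprintf("  mean orientation %.1f deg, mean eccentricity %.3f\n",
                mean_orientation(a), mean(x$eccentricity_map, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.alignment_maps <- function(x, ...) {
  g <- expand.grid(window_row = x$window_rows, window_col = x$window_cols)
  data.frame(g, angle_deg = as.vector(x$angle_map),
             eccentricity = as.vector(x$eccentricity_map))
}

#' Circular variance of axial (period-180) orientation data
#'
#' `V = 1 - |sum(w * exp(2i*theta))| / sum(w)` on doubled angles: 1 for a
#' perfectly isotropic orientation distribution, 0 when all weight lies on
#' one orientation. Two equal weights 90 degrees apart also give 1 (their
#' doubled angles are antipodal).
#'
#' @param angles_deg orientations in degrees (interpreted modulo 180).
#' @param weights optional non-negative weights, not all zero.
#' @return value in \[0, 1\].
#' @export
circular_variance <- function(angles_deg, weights = NULL) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (!length(angles_deg)) stop("no orientations supplied")
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  z <- sum(weights * exp(2i * angles_deg * pi / 180))
  1 - Mod(z) / sum(weights)
}

#' Mean orientation of axial data
#'
#' Half the argument of the doubled-angle resultant, mapped to \[0, 180),
#' optionally shifted into another reporting frame (e.g. `frame_offset_deg
#' = 90` for conventions whose zero is perpendicular to ours).
#'
#' @inheritParams circular_variance
#' @param frame_offset_deg added to the result modulo 180 (default 0).
#' @return degrees in \[0, 180); `NA` with a warning if the resultant
#'   length is (numerically) zero, in which case the mean is undefined.
#' @export
mean_orientation <- function(angles_deg, weights = NULL,
                             frame_offset_deg = 0) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (!length(angles_deg)) stop("no orientations supplied")
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  z <- sum(weights * exp(2i * angles_deg * pi / 180))
  if (Mod(z) / sum(weights) < 1e-12) {
    warning("zero resultant length; mean orientation undefined")
    return(NA_real_)
  }
  ((Arg(z) / 2) * 180 / pi + frame_offset_deg) %% 180
}

#' Orientation distribution of an image's Fourier power spectrum
#'
#' Accumulates the centred Fourier magnitude into 1-degree orientation bins
#' over the requested ring range (DC excluded), reported in the real-space
#' fibre frame (the 90-degree Fourier rotation is already applied). This is
#' the whole-image orientation summary used with [circular_variance()] and
#' [mean_orientation()] to emulate spectral orientation-distribution
#' analyses of fibre images.
#'
#' @param img numeric matrix.
#' @param r_min,r_max ring range. The defaults, ring 2 to half the Nyquist
#'   ring, bracket the structure-bearing band of PSF-blurred micrographs:
#'   DC and ring 1 carry field-level intensity structure, and rings beyond
#'   half-Nyquist are dominated by flat detection noise.
#' @return list with `angles_deg` (bin centres 0.5..179.5) and `weights`.
#' @export
orientation_distribution <- function(img, r_min = 2, r_max = NULL) {
  img <- as.matrix(img)
  m <- nrow(img); n <- ncol(img)
  nyq <- floor(min(m, n) / 2) - 1
  if (is.null(r_max)) r_max <- floor(min(m, n) / 4)
  stopifnot(r_min >= 1, r_max <= nyq, r_min < r_max)
  w <- fftshift2(Mod(stats::fft(img)))
  cy <- floor(m / 2) + 1
  cx <- floor(n / 2) + 1
  dy <- matrix(seq_len(m) - cy, m, n)
  dx <- matrix(seq_len(n) - cx, m, n, byrow = TRUE)
  g <- freq_grids(m, n)
  keep <- round(g$r) >= r_min & round(g$r) <= r_max
  # physical frequency-plane angle, then rotate 90 deg into the fibre frame
  theta <- atan2(-dy[keep] / m, dx[keep] / n) * 180 / pi
  fibre_angle <- (theta + 90) %% 180
  bins <- factor(pmin(floor(fibre_angle), 179), levels = 0:179)
  weights <- vapply(split(w[keep], bins), sum, numeric(1))
  # per-bin pixel counts carry a 4-fold lattice structure (orthogonal to
  # the doubled-angle moments); exposed for count-normalised diagnostics
  list(angles_deg = 0:179 + 0.5, weights = unname(weights),
       n_pixels = unname(as.vector(table(bins))))
}

#' Rayleigh test of uniformity for axial orientation data
#'
#' Tests the null hypothesis that orientations are uniform on \[0, 180)
#' using the resultant length of the doubled angles, with the standard
#' finite-sample correction to the asymptotic p-value.
#'
#' @param angles_deg orientations in degrees.
#' @return list with `statistic` (Z = n * Rbar^2), `r_bar`, `p_value`, `n`.
#' @export
rayleigh_test <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n <- length(angles_deg)
  if (n < 2) stop("need at least 2 orientations")
  r_bar <- Mod(mean(exp(2i * angles_deg * pi / 180)))
  z <- n * r_bar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(statistic = z, r_bar = r_bar, p_value = max(min(p, 1), 0), n = n)
}

#' Two-sample Kuiper test for circular (orientation) data
#'
#' Rotation-invariant two-sample test comparing the empirical distributions
#' of two angle samples on the circle; orientations (period 180) are mapped
#' through the doubled-angle transform first. The p-value uses the
#' asymptotic Kuiper series with the Stephens effective-sample-size
#' correction.
#'
#' @param angles1_deg,angles2_deg the two orientation samples, degrees.
#' @param axial if `TRUE` (default) treat input as axial data with period
#'   180 and double the angles.
#' @return list with `statistic` (V = D+ + D-), `p_value`, `n1`, `n2`.
#' @export
kuiper_test <- function(angles1_deg, angles2_deg, axial = TRUE) {
  a1 <- angles1_deg[!is.na(angles1_deg)]
  a2 <- angles2_deg[!is.na(angles2_deg)]
  if (length(a1) < 3 || length(a2) < 3)
    stop("need at least 3 orientations per sample")
  period <- if (axial) 180 else 360
  u1 <- sort((a1 %% period) / period)
  u2 <- sort((a2 %% period) / period)
  all_u <- sort(unique(c(u1, u2)))
  e1 <- vapply(all_u, function(u) mean(u1 <= u), numeric(1))
  e2 <- vapply(all_u, function(u) mean(u2 <= u), numeric(1))
  v <- max(e1 - e2) + max(e2 - e1)
  ne <- length(u1) * length(u2) / (length(u1) + length(u2))
  lambda <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * v
  k <- 1:100
  p <- 2 * sum((4 * k^2 * lambda^2 - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = v, p_value = max(min(p, 1), 0),
       n1 = length(u1), n2 = length(u2))
}
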