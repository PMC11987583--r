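#' Forward 2-D discrete Fourier transform of an image
#'
#' Standard unnormalised DFT (the inverse divides by `m*n`, so a round trip
#' is the identity to float precision). The result is returned in uncentred
#' layout with the centring state tracked explicitly.
#'
#' @param img numeric matrix, at least 8 x 8 for spectral operations.
#' @return object of class `fourier_image` with fields `values` (complex
#'   matrix) and `centred` (logical).
#' @export
fourier_transform <- function(img) {
  img <- as.matrix(img)
  stopifnot(is.numeric(img), all(is.finite(img)))
  structure(list(values = stats::fft(img), centred = FALSE),
            class = "fourier_image")
}

#' Inverse 2-D discrete Fourier transform
#'
#' @param fi an uncentred `fourier_image` (use [decentre_spectrum()] first
#'   if needed).
#' @return real numeric matrix.
#' @export
inverse_fourier_transform <- function(fi) {
  stopifnot(inherits(fi, "fourier_image"))
  if (fi$centred)
    stop("decentre the transform before inverting")
  Re(stats::fft(fi$values, inverse = TRUE)) / length(fi$values)
}

#' Bring the zero-frequency coefficient to the image centre
#'
#' Swaps quadrants so DC lands at row `floor(m/2)+1`, column `floor(n/2)+1`.
#' The centring state is tracked, never inferred: centring an already
#' centred transform is an error.
#'
#' @param fi an uncentred `fourier_image`.
#' @return centred `fourier_image`.
#' @export
centre_spectrum <- function(fi) {
  stopifnot(inherits(fi, "fourier_image"))
  if (fi$centred) stop("transform is already centred")
  structure(list(values = fftshift2(fi$values), centred = TRUE),
            class = "fourier_image")
}

#' Undo the quadrant swap of [centre_spectrum()]
#'
#' @param fi a centred `fourier_image`.
#' @return uncentred `fourier_image`; `decentre_spectrum(centre_spectrum(x))`
#'   restores `x` exactly for any dimensions.
#' @export
decentre_spectrum <- function(fi) {
  stopifnot(inherits(fi, "fourier_image"))
  if (!fi$centred) stop("transform is not centred")
  structure(list(values = ifftshift2(fi$values), centred = FALSE),
            class = "fourier_image")
}

new_anisotropy_image <- function(values, mode) {
  structure(list(values = values, centred = TRUE, mode = mode),
            class = "anisotropy_image")
}

#' @export
print.anisotropy_image <- function(x, ...) {
  cat(sprintf("<anisotropy_image> %dx%d, mode '%s', centred\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' Fourier-space anisotropy image from a polarisation-resolved pair
#'
#' Computes `FA = 1 + (|Yv| - |Yh|) / (|Yv| + |Yh|)` per Fourier
#' coefficient, after dividing the designated channel by the detection
#' G factor. Taking magnitudes discards all positional information (phase),
#' so the result is robust to small misalignment between channels. Values
#' above 1 mark scales/orientations brighter in the vertical channel.
#'
#' @param img_h,img_v horizontal and vertical detection-channel images
#'   (equal-sized numeric matrices).
#' @param g_factor relative detection efficiency of the two channels
#'   (e.g. 1.13); the `which_divided` channel is divided by it first.
#' @param which_divided `"horizontal"` (default) or `"vertical"`.
#' @return centred `anisotropy_image` in `"pair"` mode; values in \[0, 2\].
#'   Coefficients where both magnitudes vanish are set to the neutral value 1.
#' @export
anisotropy_pair <- function(img_h, img_v, g_factor = 1,
                            which_divided = c("horizontal", "vertical")) {
  which_divided <- match.arg(which_divided)
  stopifnot(g_factor > 0)
  img_h <- as.matrix(img_h); img_v <- as.matrix(img_v)
  if (!all(dim(img_h) == dim(img_v)))
    stop("channel images must have identical dimensions")
  if (which_divided == "horizontal") img_h <- img_h / g_factor
  else img_v <- img_v / g_factor
  ah <- Mod(stats::fft(img_h))
  av <- Mod(stats::fft(img_v))
  denom <- av + ah
  zero <- denom == 0
  if (any(zero)) {
    message(sum(zero), " coefficient(s) with zero magnitude in both ",
            "channels set to neutral FA = 1")
    denom[zero] <- 1
  }
  fa <- 1 + (av - ah) / denom
  fa[zero] <- 1
  new_anisotropy_image(fftshift2(fa), mode = "pair")
}

#' Fourier-magnitude image of a single micrograph
#'
#' `FA = |Y|` of the (single, non-polarisation-resolved) image: it carries
#' orientation information from both the excitation-polarisation bias and
#' any intrinsic fibre alignment, which is why it must be measured on an
#' intrinsically unaligned calibration sample when estimating the
#' excitation operator.
#'
#' @param img numeric matrix.
#' @return centred `anisotropy_image` in `"single"` mode (values >= 0).
#' @export
anisotropy_single <- function(img) {
  img <- as.matrix(img)
  new_anisotropy_image(fftshift2(Mod(stats::fft(img))), mode = "single")
}

#' Sample a Fourier ring profile
#'
#' Reads FA values around the ring of a given spatial-frequency radius by
#' nearest-pixel lookup at `(centre_row - r_row*sin(theta),
#' centre_col + r_col*cos(theta))` for angles uniform on \[0, 2*pi). For
#' non-square images the ring becomes an ellipse with semi-axes scaled by
#' the image aspect, and the radius indexes the major axis.
#'
#' @param fa a centred `anisotropy_image`.
#' @param radius integer ring radius, `1 <= radius <= floor(min(m,n)/2) - 1`.
#' @param n_angles number of angular samples; default `max(16, ceil(2*pi*r))`
#'   so arc spacing is about one pixel.
#' @return object of class `ring_profile` with fields `radius`,
#'   `thetas_rad`, `samples`.
#' @export
extract_ring <- function(fa, radius, n_angles = NULL) {
  stopifnot(inherits(fa, "anisotropy_image"), fa$centred)
  m <- nrow(fa$values); n <- ncol(fa$values)
  r_max <- floor(min(m, n) / 2) - 1
  if (radius < 1 || radius > r_max)
    stop(sprintf("radius must be in [1, %d]", r_max))
  if (is.null(n_angles)) n_angles <- max(16, ceiling(2 * pi * radius))
  mx <- max(m, n)
  r_row <- radius * m / mx
  r_col <- radius * n / mx
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[seq_len(n_angles)]
  cy <- floor(m / 2) + 1
  cx <- floor(n / 2) + 1
  rows <- round(cy - r_row * sin(th))
  cols <- round(cx + r_col * cos(th))
  structure(list(radius = radius, thetas_rad = th,
                 samples = fa$values[cbind(rows, cols)]),
            class = "ring_profile")
}

#' Second-order anisotropy moments of a ring profile
#'
#' `gamma_c = sum(FA * cos(2*theta)) / sum(FA)` and the analogous sine
#' moment. For a profile of the photoselection form
#' `a0*(1 + A*cos(2*(theta - theta0)))` these evaluate to
#' `(A/2)*cos(2*theta0)` and `(A/2)*sin(2*theta0)`.
#'
#' @param profile a [extract_ring()] result.
#' @return named numeric vector `c(gamma_c, gamma_s)`. If the profile sums
#'   to zero or less the moments are undefined and returned as 0 with a
#'   warning.
#' @export
ring_moments <- function(profile) {
  stopifnot(inherits(profile, "ring_profile"))
  s <- sum(profile$samples)
  if (!is.finite(s) || s <= 0) {
    warning("non-positive ring profile sum; moments set to 0")
    return(c(gamma_c = 0, gamma_s = 0))
  }
  c(gamma_c = sum(profile$samples * cos(2 * profile$thetas_rad)) / s,
    gamma_s = sum(profile$samples * sin(2 * profile$thetas_rad)) / s)
}

#' Least-squares second-order series fit of a ring profile
#'
#' Fits `a0/2 + a2*cos(2*theta) + b2*sin(2*theta)` to the sampled profile.
#' The moments of [ring_moments()] are the primary per-ring summary; this
#' fit is provided for inspection (note `a2/(a0/2) = 2*gamma_c` for an
#' ideal profile).
#'
#' @param profile a `ring_profile`.
#' @return named vector `c(a0, a2, b2)`.
#' @export
fit_ring_series <- function(profile) {
  stopifnot(inherits(profile, "ring_profile"))
  th <- profile$thetas_rad
  fit <- stats::lm(profile$samples ~ cos(2 * th) + sin(2 * th))
  cf <- unname(coef(fit))
  c(a0 = 2 * cf[1], a2 = cf[2], b2 = cf[3])
}

#' Anisotropy moment spectra over all ring radii
#'
#' Evaluates the cosine and sine anisotropy moments at every integer ring
#' radius in range, producing the per-spatial-frequency spectra
#' `gamma_c(f)`, `gamma_s(f)`. The DC ring (r = 0) is always excluded.
#'
#' @param fa a centred `anisotropy_image` (pair or single mode).
#' @param r_min,r_max inclusive ring range; defaults 1 to
#'   `floor(min(m,n)/2) - 1`.
#' @return object of class `anisotropy_spectrum` with fields `frequencies`,
#'   `gamma_c`, `gamma_s`, `n_samples`, `mode`, `source_shape`.
#' @export
anisotropy_spectrum <- function(fa, r_min = 1, r_max = NULL) {
  stopifnot(inherits(fa, "anisotropy_image"), fa$centred)
  m <- nrow(fa$values); n <- ncol(fa$values)
  nyq <- floor(min(m, n) / 2) - 1
  if (is.null(r_max)) r_max <- nyq
  stopifnot(r_min >= 1, r_min < r_max, r_max <= nyq)
  radii <- r_min:r_max
  gc <- gs <- ns <- numeric(length(radii))
  for (i in seq_along(radii)) {
    prof <- extract_ring(fa, radii[i])
    mom <- ring_moments(prof)
    gc[i] <- mom[["gamma_c"]]
    gs[i] <- mom[["gamma_s"]]
    ns[i] <- length(prof$samples)
  }
  structure(list(frequencies = radii, gamma_c = gc, gamma_s = gs,
                 n_samples = ns, mode = fa$mode, source_shape = c(m, n)),
            class = "anisotropy_spectrum")
}

#' @export
print.anisotropy_spectrum <- function(x, ...) {
  cat(sprintf(
    "<anisotropy_spectrum> mode '%s', rings %d..%d of %dx%d image\n",
    x$mode, min(x$frequencies), max(x$frequencies),
    x$source_shape[1], x$source_shape[2]))
  cat(sprintf("  |gamma_c| max %.4f, |gamma_s| max %.4f\n",
              max(abs(x$gamma_c)), max(abs(x$gamma_s))))
  invisible(x)
}

#' @export
as.data.frame.anisotropy_spectrum <- function(x, ...) {
  data.frame(ring_index = x$frequencies,
             freq_per_pixel = x$frequencies / max(x$source_shape),
             gamma_c = x$gamma_c, gamma_s = x$gamma_s,
             n_samples = x$n_samples)
}

#' Steady-state anisotropy from the Perrin relation
#'
#' `R = R0 / (1 + tau_f / tau_rot)`: the measured fluorescence anisotropy
#' of a fluorophore with fundamental anisotropy `R0`, fluorescence lifetime
#' `tau_f` and rotational diffusion time `tau_rot`. Fast rotation
#' (`tau_rot << tau_f`) depolarises emission completely (R -> 0);
#' immobilised fluorophores (`tau_rot >> tau_f`) retain R -> R0.
#'
#' @param r0 fundamental anisotropy.
#' @param tau_f fluorescence lifetime (same units as `tau_rot`, e.g. ns).
#' @param tau_rot rotational diffusion time.
#' @return measured anisotropy R.
#' @export
perrin_anisotropy <- function(r0, tau_f, tau_rot) {
  if (any(tau_f <= 0) || any(tau_rot <= 0))
    stop("lifetimes must be positive")
  r0 / (1 + tau_f / tau_rot)
}
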