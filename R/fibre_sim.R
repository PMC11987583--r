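#' Simulation recipe for a synthetic fibre micrograph
#'
#' Bundles all parameters of the fibre-field simulator. The defaults are the
#' reference simulation used throughout the package's validation: 50,000
#' fibres with orientations uniform on \[0, 180) degrees and lengths uniform
#' on \[50, 250\] pixels, positioned uniformly on a 5000 x 5000 pixel canvas,
#' each carrying 1000 counts per fibre pixel, blurred with a Gaussian PSF of
#' sigma = 13 pixels, block-averaged 5-fold (yielding a 1000 x 1000 image
#' with a 100 nm effective pixel), then Poisson noise followed by additive
#' Gaussian read noise (mean 20, sd 2 counts).
#'
#' @param canvas_px integer length-2, pre-downsampling canvas (rows, cols).
#' @param n_fibres number of fibres.
#' @param length_range_px length-2, min/max fibre length in canvas pixels.
#' @param base_signal photon counts deposited per fibre pixel.
#' @param blur_sigma_px Gaussian PSF sigma on the canvas, pixels.
#' @param downsample integer block-averaging factor (>= 1).
#' @param gauss_noise_mean,gauss_noise_sd additive read-noise parameters.
#' @param background additive counts per (downsampled) pixel, applied before
#'   Poisson noise.
#' @param angle_range_deg length-2 allowed fibre orientations; restricting
#'   the range simulates intrinsic alignment. `lo` may be negative (width at
#'   most 180): sampled angles are wrapped modulo 180, so e.g. `c(-75, 75)`
#'   gives a horizontally aligned population.
#' @param seed master integer seed; expands into independent geometry and
#'   noise streams.
#' @return an object of class `sim_recipe`.
#' @seealso [matlab_recipe()] for the coarse-PSF variant with constant
#'   background, [simulate_field()], [render_image()].
#' @export
fibre_recipe <- function(canvas_px = c(5000, 5000),
                         n_fibres = 50000,
                         length_range_px = c(50, 250),
                         base_signal = 1000,
                         blur_sigma_px = 13,
                         downsample = 5,
                         gauss_noise_mean = 20,
                         gauss_noise_sd = 2,
                         background = 0,
                         angle_range_deg = c(0, 180),
                         seed = 1) {
  canvas_px <- rep_len(as.integer(canvas_px), 2)
  stopifnot(
    all(canvas_px >= 8),
    n_fibres >= 0,
    length(length_range_px) == 2,
    length_range_px[1] <= length_range_px[2],
    length_range_px[1] > 0,
    base_signal >= 0,
    blur_sigma_px >= 0,
    downsample >= 1,
    gauss_noise_mean >= 0, gauss_noise_sd >= 0, background >= 0,
    length(angle_range_deg) == 2,
    angle_range_deg[1] < angle_range_deg[2],
    diff(angle_range_deg) <= 180,
    angle_range_deg[2] <= 180
  )
  structure(
    list(canvas_px = canvas_px, n_fibres = as.integer(n_fibres),
         length_range_px = as.numeric(length_range_px),
         base_signal = base_signal, blur_sigma_px = blur_sigma_px,
         downsample = as.integer(downsample),
         gauss_noise_mean = gauss_noise_mean,
         gauss_noise_sd = gauss_noise_sd, background = background,
         angle_range_deg = as.numeric(angle_range_deg),
         seed = as.integer(seed)),
    class = "sim_recipe"
  )
}

#' Coarse-PSF simulation recipe with constant background
#'
#' Variant of [fibre_recipe()] emulating acquisition at native pixel size:
#' no downsampling, a PSF of 2.7 pixels FWHM, a constant background of 10
#' counts and a fibre brightness chosen to give roughly 10:1 peak
#' signal-to-noise per fibre under Poisson statistics.
#'
#' @param canvas_px canvas size (rows, cols), default 512 x 512.
#' @param n_fibres fibre count; default keeps the areal density of the
#'   reference recipe (50,000 per 5000^2).
#' @param seed master seed.
#' @param ... further overrides passed to [fibre_recipe()].
#' @return a `sim_recipe`.
#' @export
matlab_recipe <- function(canvas_px = c(512, 512),
                          n_fibres = NULL,
                          seed = 1, ...) {
  canvas_px <- rep_len(as.integer(canvas_px), 2)
  if (is.null(n_fibres))
    n_fibres <- max(1L, round(50000 * prod(canvas_px) / 5000^2))
  fibre_recipe(canvas_px = canvas_px, n_fibres = n_fibres,
               base_signal = 320, blur_sigma_px = 2.7 / (2 * sqrt(2 * log(2))),
               downsample = 1, gauss_noise_mean = 0, gauss_noise_sd = 0,
               background = 10, seed = seed, ...)
}

#' @export
print.sim_recipe <- function(x, ...) {
  cat(sprintf(
    "<sim_recipe> %d fibres on %dx%d canvas, angles [%g,%g)deg,\n",
    x$n_fibres, x$canvas_px[1], x$canvas_px[2],
    x$angle_range_deg[1], x$angle_range_deg[2]))
  cat(sprintf(
    "  lengths [%g,%g]px, signal %g, PSF sigma %g px, downsample %d,\n",
    x$length_range_px[1], x$length_range_px[2], x$base_signal,
    x$blur_sigma_px, x$downsample))
  cat(sprintf("  background %g, Gaussian noise (%g, %g), seed %d\n",
              x$background, x$gauss_noise_mean, x$gauss_noise_sd, x$seed))
  invisible(x)
}

#' Orientation-dependent excitation settings
#'
#' Describes how polarised excitation modulates the brightness of a fibre at
#' orientation theta_f. Two operator forms are supported, differing in their
#' baseline and admissible strength:
#' * `"difference"`: multiplier `1 + P * (cos^2(d) - sin^2(d))`
#'   `= 1 + P * cos(2d)`, `d = theta_f - theta_p`, with `P` in \[0, 1\];
#' * `"cos2"`: multiplier `1 + P * cos^2(d)`, any `P >= 0`.
#'
#' @param angle_deg polarisation axis theta_p, degrees (0 = horizontal,
#'   anticlockwise positive).
#' @param strength modulation strength `P` (range depends on `variant`).
#' @param variant `"difference"` or `"cos2"`.
#' @param gradient if `TRUE`, the strength varies linearly from 0 at the left
#'   image edge to `strength` at the right edge, evaluated at each fibre's
#'   origin column (emulates spatially varying illumination polarisation).
#' @return an object of class `pol_settings`.
#' @export
polarisation <- function(angle_deg, strength,
                         variant = c("difference", "cos2"),
                         gradient = FALSE) {
  variant <- match.arg(variant)
  if (variant == "difference" && (strength < 0 || strength > 1))
    stop("'difference' variant requires strength in [0, 1]")
  if (variant == "cos2" && strength < 0)
    stop("'cos2' variant requires strength >= 0")
  structure(list(angle_deg = angle_deg, strength = strength,
                 variant = variant, gradient = isTRUE(gradient)),
            class = "pol_settings")
}

#' Brightness multiplier for a fibre under polarised excitation
#'
#' @param angle_f_deg fibre orientation(s), degrees.
#' @param settings a [polarisation()] object (or `NULL` for no modulation).
#' @param strength_scale optional per-fibre scaling of the strength (used by
#'   the gradient option); default 1.
#' @return positive multiplier(s), same length as `angle_f_deg`.
#' @export
polarisation_factor <- function(angle_f_deg, settings, strength_scale = 1) {
  if (is.null(settings)) return(rep(1, length(angle_f_deg)))
  if (!inherits(settings, "pol_settings"))
    stop("'settings' must be created with polarisation()")
  d <- (angle_f_deg - settings$angle_deg) * pi / 180
  s <- settings$strength * strength_scale
  switch(settings$variant,
    difference = 1 + s * cos(2 * d),
    cos2       = 1 + s * cos(d)^2,
    stop("unknown polarisation variant: ", settings$variant)
  )
}

#' Draw a random fibre field from a recipe
#'
#' Samples `n_fibres` fibres with orientations uniform on the recipe's angle
#' range (wrapped modulo 180), lengths uniform on the length range and
#' centres uniform on the canvas. Fibres may overlap. The same recipe (same
#' seed) always yields the identical field.
#'
#' @param recipe a [fibre_recipe()].
#' @return object of class `fibre_field`: a data frame with columns
#'   `fibre_id`, `angle_deg`, `length_px`, `row`, `col`, `base_signal`, with
#'   the recipe attached as attribute `"recipe"`.
#' @export
simulate_field <- function(recipe) {
  stopifnot(inherits(recipe, "sim_recipe"))
  n <- recipe$n_fibres
  field <- with_seed(derive_seed(recipe$seed, "geometry"), {
    data.frame(
      fibre_id = seq_len(n),
      angle_deg = runif(n, recipe$angle_range_deg[1],
                        recipe$angle_range_deg[2]) %% 180,
      length_px = runif(n, recipe$length_range_px[1],
                        recipe$length_range_px[2]),
      row = runif(n, 1, recipe$canvas_px[1]),
      col = runif(n, 1, recipe$canvas_px[2])
    )
  })
  if (n == 0)
    field <- data.frame(fibre_id = integer(), angle_deg = numeric(),
                        length_px = numeric(), row = numeric(),
                        col = numeric())
  field$base_signal <- rep(recipe$base_signal, n)
  structure(field, recipe = recipe, class = c("fibre_field", "data.frame"))
}

#' @export
print.fibre_field <- function(x, ...) {
  r <- attr(x, "recipe")
  cat(sprintf("<fibre_field> %d fibres on %dx%d canvas\n",
              nrow(x), r$canvas_px[1], r$canvas_px[2]))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more\n", nrow(x) - 5))
  invisible(x)
}

# Anti-aliased rasterisation of 1-pixel-wide fibres onto the canvas.
# Each fibre is stepped at unit spacing along its major axis and deposited
# by bilinear splatting onto the four neighbouring pixels, so the total
# deposit is amplitude * length regardless of orientation (no
# angle-dependent aliasing). Accumulation across fibres uses sparse-matrix
# summation in chunks to stay fast without collisions.
rasterise_field <- function(field, amplitude, chunk = 2000L) {
  recipe <- attr(field, "recipe")
  m <- recipe$canvas_px[1]; n <- recipe$canvas_px[2]
  canvas <- matrix(0, m, n)
  nf <- nrow(field)
  if (nf == 0) return(canvas)
  if (min(m, n) < max(field$length_px))
    warning("canvas smaller than the longest fibre; fibres clipped at borders")
  th <- field$angle_deg * pi / 180
  dc <- cos(th); dr <- -sin(th)   # 0 deg = +column axis, anticlockwise +
  for (start in seq(1L, nf, by = chunk)) {
    ii <- start:min(start + chunk - 1L, nf)
    Ri <- Ci <- Wi <- vector("list", length(ii))
    k <- 1L
    for (f in ii) {
      tstep <- 1 / max(abs(dc[f]), abs(dr[f]))
      tt <- seq(-field$length_px[f] / 2, field$length_px[f] / 2, by = tstep)
      r <- field$row[f] + tt * dr[f]
      c <- field$col[f] + tt * dc[f]
      rf <- floor(r); cf <- floor(c)
      fr <- r - rf;   fc <- c - cf
      w0 <- amplitude[f] * tstep
      R <- c(rf, rf + 1, rf,     rf + 1)
      C <- c(cf, cf,     cf + 1, cf + 1)
      W <- w0 * c((1 - fr) * (1 - fc), fr * (1 - fc),
                  (1 - fr) * fc,       fr * fc)
      ok <- R >= 1 & R <= m & C >= 1 & C <= n & W > 0
      Ri[[k]] <- R[ok]; Ci[[k]] <- C[ok]; Wi[[k]] <- W[ok]
      k <- k + 1L
    }
    sm <- Matrix::sparseMatrix(i = unlist(Ri), j = unlist(Ci),
                               x = unlist(Wi), dims = c(m, n))
    canvas <- canvas + as.matrix(sm)
  }
  canvas
}

# PSF blur + block-average downsampling shared by all render paths
blur_downsample <- function(canvas, blur_sigma, downsample) {
  if (blur_sigma > 0) {
    canvas <- EBImage::gblur(canvas, sigma = blur_sigma)
    canvas <- EBImage::imageData(EBImage::Image(canvas))
  }
  f <- downsample
  if (f > 1) {
    m <- nrow(canvas); n <- ncol(canvas)
    m2 <- ceiling(m / f) * f; n2 <- ceiling(n / f) * f
    if (m2 > m || n2 > n) {       # zero-pad right/bottom to a multiple
      padded <- matrix(0, m2, n2)
      padded[seq_len(m), seq_len(n)] <- canvas
      canvas <- padded
    }
    a <- aperm(array(canvas, c(f, m2 / f, f, n2 / f)), c(1, 3, 2, 4))
    canvas <- colMeans(a, dims = 2)
  }
  canvas
}

# shared noise stage; streams keyed so paired channels get independent noise
apply_noise <- function(img, recipe, seed, stream_suffix = "") {
  img <- img + recipe$background
  img <- with_seed(derive_seed(seed, paste0("poisson", stream_suffix)), {
    matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  })
  if (recipe$gauss_noise_sd > 0 || recipe$gauss_noise_mean > 0) {
    img <- img + with_seed(
      derive_seed(seed, paste0("gauss", stream_suffix)),
      matrix(rnorm(length(img), recipe$gauss_noise_mean,
                   recipe$gauss_noise_sd), nrow(img), ncol(img)))
  }
  img
}

#' Render a fibre field into a synthetic micrograph
#'
#' Rasterises each fibre as an anti-aliased 1-pixel-wide line at
#' `base_signal * polarisation_factor` counts per fibre pixel, convolves
#' with the Gaussian PSF, block-averages by the downsampling factor, adds
#' the constant background, then applies Poisson noise followed by additive
#' Gaussian noise. The returned float matrix is not clipped (Gaussian noise
#' may make pixels negative); quantisation happens only on explicit
#' 16-bit export via [write_image()].
#'
#' @param field a [simulate_field()] result.
#' @param settings optional [polarisation()] settings; `NULL` renders the
#'   unbiased ground truth.
#' @param seed seed for the noise streams; defaults to the recipe seed.
#' @param noise set `FALSE` to skip background and both noise stages
#'   (useful for ground-truth and flux checks).
#' @return numeric matrix of size `canvas_px / downsample`, with attribute
#'   `pixel_size_factor = downsample` recorded in `attr(,"downsample")`.
#' @export
render_image <- function(field, settings = NULL, seed = NULL, noise = TRUE) {
  stopifnot(inherits(field, "fibre_field"))
  recipe <- attr(field, "recipe")
  if (is.null(seed)) seed <- recipe$seed
  scale <- if (!is.null(settings) && settings$gradient)
    field$col / recipe$canvas_px[2] else 1
  amp <- field$base_signal *
    polarisation_factor(field$angle_deg, settings, strength_scale = scale)
  if (any(amp < 0)) amp <- pmax(amp, 0)
  img <- rasterise_field(field, amp)
  img <- blur_downsample(img, recipe$blur_sigma_px, recipe$downsample)
  if (noise) img <- apply_noise(img, recipe, seed)
  attr(img, "downsample") <- recipe$downsample
  img
}

#' Render a polarisation-resolved image pair of one fibre field
#'
#' Produces horizontal- and vertical-detection channel images of the same
#' field, emulating emission polarised parallel to the fibre axis: a fibre
#' at orientation theta_f is weighted by `1 + s*cos(2*theta_f)` in the
#' horizontal channel and `1 - s*cos(2*theta_f)` in the vertical channel
#' (horizontal fibres brighter in the horizontal channel). The two channels
#' share fibre geometry but receive independent noise.
#'
#' @param field a [simulate_field()] result.
#' @param emission_strength s in \[0, 1\].
#' @param seed noise seed; defaults to the recipe seed.
#' @return list with elements `horizontal` and `vertical` (numeric matrices).
#' @export
simulate_polarised_pair <- function(field, emission_strength, seed = NULL) {
  stopifnot(inherits(field, "fibre_field"))
  if (emission_strength < 0 || emission_strength > 1)
    stop("emission_strength must be in [0, 1]")
  recipe <- attr(field, "recipe")
  if (is.null(seed)) seed <- recipe$seed
  c2 <- cos(2 * field$angle_deg * pi / 180)
  render_channel <- function(weight, suffix) {
    img <- rasterise_field(field, field$base_signal * weight)
    img <- blur_downsample(img, recipe$blur_sigma_px, recipe$downsample)
    apply_noise(img, recipe, seed, stream_suffix = suffix)
  }
  list(horizontal = render_channel(1 + emission_strength * c2, "-h"),
       vertical   = render_channel(1 - emission_strength * c2, "-v"))
}
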