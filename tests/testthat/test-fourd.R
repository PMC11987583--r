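make_spec <- function(frequencies, gamma_c, gamma_s, shape = c(64, 64)) {
  structure(list(frequencies = frequencies,
                 gamma_c = rep_len(gamma_c, length(frequencies)),
                 gamma_s = rep_len(gamma_s, length(frequencies)),
                 n_samples = rep(360L, length(frequencies)),
                 mode = "single", source_shape = shape),
            class = "anisotropy_spectrum")
}

test_that("spectrum smoothing is a centred moving average", {
  sp <- make_spec(1:5, 0, 0)
  sp$gamma_c <- c(0, 0, 1, 0, 0)
  sm <- smooth_spectrum(sp, 3)
  expect_equal(sm$gamma_c, c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  expect_identical(smooth_spectrum(sp, 1), sp)
  const <- make_spec(1:9, 0.2, -0.1)
  expect_equal(smooth_spectrum(const, 5)$gamma_c, rep(0.2, 9))
  expect_error(smooth_spectrum(sp, 2), "odd")
})

test_that("mean_spectrum averages per ring and validates inputs", {
  a <- make_spec(1:4, 0.2, 0); b <- make_spec(1:4, 0.4, 0.2)
  m <- mean_spectrum(list(a, b))
  expect_equal(m$gamma_c, rep(0.3, 4))
  expect_equal(m$gamma_s, rep(0.1, 4))
  expect_error(mean_spectrum(list(a, make_spec(1:5, 0, 0))), "ring range")
})

test_that("inverse operator reconstructs and inverts the ring profile", {
  # zero spectrum: identity operator
  op0 <- inverse_operator(make_spec(1:31, 0, 0), c(64, 64))
  expect_true(all(op0$values == 1))
  # gamma_c = 0.25: profile amplitude 0.5, so 2/3 at theta=0, 2 at 90 deg
  op <- inverse_operator(make_spec(1:31, 0.25, 0), c(64, 64),
                         start_radius = 1)
  cen <- fourd:::fftshift2(op$values)
  ctr <- 33
  expect_equal(cen[ctr, ctr + 10], 1 / 1.5, tolerance = 1e-12) # theta = 0
  expect_equal(cen[ctr - 10, ctr], 2, tolerance = 1e-12)       # theta = 90
  expect_equal(cen[ctr, ctr], 1)                               # DC untouched
  # rings below start_radius stay exactly 1
  op2 <- inverse_operator(make_spec(1:31, 0.25, 0), c(64, 64),
                          start_radius = 4)
  cen2 <- fourd:::fftshift2(op2$values)
  expect_equal(cen2[ctr, ctr + 2], 1)
  expect_lt(cen2[ctr, ctr + 10], 1)
  # all values positive
  expect_true(all(op$values > 0))
})

test_that("operator times the bias profile it models cancels to one", {
  set.seed(9)
  gc <- runif(31, -0.1, 0.2); gs <- runif(31, -0.15, 0.15)
  sp <- make_spec(1:31, 0, 0); sp$gamma_c <- gc; sp$gamma_s <- gs
  op <- inverse_operator(sp, c(64, 64), start_radius = 1, clamp_floor = 1e-6)
  g <- fourd:::freq_grids(64, 64)
  ring <- round(g$r)
  idx <- pmin(pmax(ring, 1), 31)
  bias <- 1 + 2 * gc[idx] * g$cos2t + 2 * gs[idx] * g$sin2t
  prod <- fourd:::fftshift2(op$values) * bias
  active <- ring >= 1 & ring <= 31
  expect_lt(max(abs(prod[active] - 1)), 0.01)
})

test_that("moments too large for the model trigger the clamp warning", {
  expect_warning(inverse_operator(make_spec(1:31, 0.45, 0.3), c(64, 64)),
                 "clamped")
})

test_that("correction preserves phase, energy and shape checks", {
  set.seed(10)
  img <- matrix(runif(64 * 64, 10, 50), 64, 64)
  id_op <- inverse_operator(make_spec(1:31, 0, 0), c(64, 64))
  out <- correct_image(img, id_op)
  expect_lt(max(abs(out - img)), 1e-10 * max(img))
  expect_equal(sum(out), sum(img))           # energy conserved exactly
  sp <- make_spec(1:31, 0.1, -0.05)
  op <- inverse_operator(sp, c(64, 64))
  corr <- correct_image(img, op)
  y0 <- stats::fft(img); y1 <- stats::fft(corr)
  big <- Mod(y0) > 1e-6 * max(Mod(y0))
  dphase <- Arg(y1[big] * Conj(y0[big]))
  expect_lt(max(abs(dphase)), 1e-8)          # amplitudes only
  expect_error(correct_image(img[1:32, ], op), "shapes differ")
})

test_that("calibration spectrum recovers the polarisation axis", {
  for (case in list(c(0.2, 80), c(0.4, 30), c(0.3, 135), c(0.3, 0))) {
    field <- simulate_field(mid_recipe(seed = 40 + case[2]))
    img <- render_image(field, polarisation(case[2], case[1], "difference"))
    sp <- calibration_spectrum(img)
    est <- implied_polarisation_angle(sp, rings = 10:60)
    delta <- abs(est - case[2]) %% 180
    expect_lt(min(delta, 180 - delta), 5)
  }
  expect_error(calibration_spectrum(matrix(1, 32, 32)), "64x64")
})

test_that("an unbiased calibration yields near-zero smoothed moments", {
  field <- simulate_field(mid_recipe(seed = 51))
  sp <- smooth_spectrum(calibration_spectrum(render_image(field, NULL)), 3)
  k <- sp$frequencies %in% 20:60
  expect_lt(max(abs(sp$gamma_c[k])), 0.06)
  expect_lt(max(abs(sp$gamma_s[k])), 0.06)
  # negative control: intrinsic alignment biases the calibration spectrum
  aligned <- simulate_field(mid_recipe(seed = 52,
                                       angle_range_deg = c(60, 120)))
  spa <- smooth_spectrum(calibration_spectrum(render_image(aligned, NULL)), 3)
  expect_gt(max(abs(spa$gamma_c[k])), 0.1)
})

test_that("self-correction drives residual moments towards zero", {
  field <- simulate_field(mid_recipe(seed = 53))
  img <- render_image(field, polarisation(80, 0.2, "difference"))
  cal <- smooth_spectrum(calibration_spectrum(img), 3)
  op <- inverse_operator(cal, dim(img), start_radius = 2)
  resid <- smooth_spectrum(calibration_spectrum(correct_image(img, op)), 3)
  k <- resid$frequencies %in% 10:60
  before <- smooth_spectrum(cal, 1)
  expect_lt(max(abs(resid$gamma_c[k])), 0.03)
  expect_lt(max(abs(resid$gamma_s[k])), 0.03)
  expect_lt(max(abs(resid$gamma_c[k])), max(abs(before$gamma_c[k])))
})

test_that("per-fibre bias correction approaches ground truth spectra", {
  # per-fibre brightness weighting is only approximately a frequency-space
  # operator; the achievable per-ring agreement sits near the speckle and
  # model-mismatch floor rather than at zero
  cal_field <- simulate_field(mid_recipe(seed = 54))
  pol <- polarisation(80, 0.2, "difference")
  cal <- smooth_spectrum(calibration_spectrum(render_image(cal_field, pol)), 3)
  test_field <- simulate_field(mid_recipe(seed = 55,
                                          angle_range_deg = c(-75, 75)))
  biased <- render_image(test_field, pol)
  truth <- render_image(test_field, NULL)
  op <- inverse_operator(cal, dim(biased), start_radius = 2)
  rc <- smooth_spectrum(calibration_spectrum(correct_image(biased, op)), 3)
  rt <- smooth_spectrum(calibration_spectrum(truth), 3)
  rb <- smooth_spectrum(calibration_spectrum(biased), 3)
  k <- rc$frequencies %in% 10:60
  err_corr <- mean(abs(rc$gamma_c[k] - rt$gamma_c[k]))
  err_raw <- mean(abs(rb$gamma_c[k] - rt$gamma_c[k]))
  expect_lt(err_corr, err_raw)     # correction moves towards ground truth
  expect_lt(err_corr, 0.05)
})

test_that("patch-wise correction at 1x1 equals the whole-frame path", {
  field <- simulate_field(tiny_recipe(seed = 56))
  cal_field <- simulate_field(tiny_recipe(seed = 57))
  img <- render_image(field)
  cal_img <- render_image(cal_field)
  pw <- patchwise_correct(img, cal_img, 1, 1, start_radius = 2,
                          smoothing = 3)
  op <- inverse_operator(
    smooth_spectrum(calibration_spectrum(cal_img), 3),
    dim(img), start_radius = 2)
  expect_equal(pw, correct_image(img, op), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(patchwise_correct(img, cal_img, 5, 5), "64 px")
  expect_error(patchwise_correct(img, cal_img[1:128, ], 2, 2), "dimensions")
})

test_that("tile bounds cover the image exactly", {
  b <- fourd:::tile_bounds(1000, 7)
  expect_equal(unname(b[1, 1]), 1)
  expect_equal(unname(b[7, 2]), 1000)
  expect_true(all(b[-1, 1] == b[-7, 2] + 1))
})

test_that("forward excitation operator biases exactly within the model", {
  ex <- excitation_operator(80, 0.2, c(64, 64), start_radius = 1)
  expect_true(all(ex$values > 0))
  set.seed(11)
  img <- matrix(runif(64 * 64, 10, 20), 64, 64)
  biased <- correct_image(img, ex)
  # measured spectrum of the biased image implies the programmed axis
  sp <- anisotropy_spectrum(anisotropy_single(biased))
  est <- implied_polarisation_angle(sp, rings = 5:25)
  delta <- abs(est - 80) %% 180
  expect_lt(min(delta, 180 - delta), 6)
})
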