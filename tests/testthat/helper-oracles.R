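# Independent brute-force oracles and small shared fixtures.

# O(N^4) direct double-sum DFT, the definition the FFT path must reproduce
dft2_brute <- function(x) {
  m <- nrow(x); n <- ncol(x)
  out <- matrix(0 + 0i, m, n)
  for (p in 0:(m - 1)) for (q in 0:(n - 1)) {
    s <- 0 + 0i
    for (j in 0:(m - 1)) for (k in 0:(n - 1))
      s <- s + exp(-2i * pi * j * p / m) * exp(-2i * pi * k * q / n) *
        x[j + 1, k + 1]
    out[p + 1, q + 1] <- s
  }
  out
}

# explicit index remap bringing DC to (floor(m/2)+1, floor(n/2)+1)
centre_brute <- function(x) {
  m <- nrow(x); n <- ncol(x)
  out <- x
  for (p in 0:(m - 1)) for (q in 0:(n - 1)) {
    out[((p + floor(m / 2)) %% m) + 1, ((q + floor(n / 2)) %% n) + 1] <-
      x[p + 1, q + 1]
  }
  out
}

# nearest-pixel ring lookup, written as a plain loop
ring_lookup_brute <- function(values, radius, n_angles) {
  m <- nrow(values); n <- ncol(values)
  mx <- max(m, n)
  cy <- floor(m / 2) + 1; cx <- floor(n / 2) + 1
  th <- (0:(n_angles - 1)) * 2 * pi / n_angles
  out <- numeric(n_angles)
  for (i in seq_len(n_angles)) {
    out[i] <- values[round(cy - radius * (m / mx) * sin(th[i])),
                     round(cx + radius * (n / mx) * cos(th[i]))]
  }
  out
}

# direct-sum second-order circular moments of a profile
moments_brute <- function(thetas, samples) {
  c(sum(samples * cos(2 * thetas)) / sum(samples),
    sum(samples * sin(2 * thetas)) / sum(samples))
}

# eigen-decomposition route to the ellipse semi-axis quantities of a
# weighted 2-D distribution (independent of the closed-form roots)
ellipse_eigen_brute <- function(w) {
  w <- w / sum(w)
  x <- matrix(seq_len(ncol(w)), nrow(w), ncol(w), byrow = TRUE)
  y <- matrix(seq_len(nrow(w)), nrow(w), ncol(w))
  xb <- sum(w * x); yb <- sum(w * y)
  cov <- matrix(c(sum(w * (x - xb)^2), sum(w * (x - xb) * (y - yb)),
                  sum(w * (x - xb) * (y - yb)), sum(w * (y - yb)^2)), 2, 2)
  sort(eigen(cov, symmetric = TRUE)$values, decreasing = TRUE)
}

# small, fast recipe used across tests (canvas kept modest on purpose)
tiny_recipe <- function(seed = 1, n_fibres = 800, ...) {
  fibre_recipe(canvas_px = c(256, 256), n_fibres = n_fibres,
               length_range_px = c(10, 50), base_signal = 500,
               blur_sigma_px = 2.6, downsample = 1, seed = seed, ...)
}

# mid-size recipe with the reference per-image-pixel fibre statistics
mid_recipe <- function(seed = 1, n_fibres = 13000, ...) {
  fibre_recipe(canvas_px = c(512, 512), n_fibres = n_fibres,
               length_range_px = c(10, 50), base_signal = 1000,
               blur_sigma_px = 2.6, downsample = 1, seed = seed, ...)
}

# synthetic image of parallel stripes at a given fibre-frame angle
stripe_patch <- function(n, angle_deg, period = 8) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)          # row index, increases downward
  th <- angle_deg * pi / 180
  # stripes run along (cos th, -sin th) in (col, row); modulate along normal
  phase <- (x * sin(th) + y * cos(th)) / period
  (cos(2 * pi * phase) > 0.8) * 1.0
}
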