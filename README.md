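# fourd

Fourier ring anisotropy and depolarisation correction for fluorescence
micrographs of labelled fibres.

## Why

Fluorophores bound to fibrillar structures (NHS-ester-labelled collagen,
phalloidin-labelled actin, ...) are often rotationally constrained, so
their excitation and emission are partially polarised along the fibre
axis. On microscopes with (even partially) polarised illumination, fibres
parallel to the polarisation appear brighter than perpendicular ones.
Automated orientation analysis (AFT, OrientationJ, CytoSpectre and
similar) then reports sample "alignment" that is really a property of the
optics - a bias that is nearly invisible by eye and survives replication.

`fourd` is for microscopists and image analysts who quantify fibre
alignment and need to detect, measure and remove this bias. It provides:

* **Fourier ring anisotropy spectra** - per-spatial-frequency orientation
  bias summarised by second-order circular moments. For each ring radius
  `f` of the (centred) Fourier-space anisotropy image `FA`,

  ```
  gamma_c(f) = sum_theta FA(f,theta) cos(2 theta) / sum_theta FA(f,theta)
  gamma_s(f) = sum_theta FA(f,theta) sin(2 theta) / sum_theta FA(f,theta)
  ```

  with `FA = 1 + (|Yv|-|Yh|)/(|Yv|+|Yh|)` for a polarisation-resolved
  image pair (G-factor corrected) or `FA = |Y|` for a single image.
* **FouRD (Fourier Ring Depolarisation)** - estimates the excitation
  operator from a calibration image of an intrinsically unaligned sample
  and cancels it with the real, positive frequency-space multiplier
  `1 / (1 + 2 gamma_c(f) cos 2 theta + 2 gamma_s(f) sin 2 theta)`,
  whole-frame or tiled (7x7) for spatially varying polarisation. Phase -
  i.e. structure - is untouched.
* **Alignment metrics** - AFT-style sliding-window angle and eccentricity
  maps (`e = sqrt(1 - b^2/a^2)` from central moments of the window power
  spectrum) and axial circular statistics (doubled-angle variance, mean
  orientation, Rayleigh and two-sample Kuiper tests).
* **A fibre-image simulator** - anti-aliased fibre fields with
  controllable intrinsic alignment, polarisation operators
  (`1 + P1 cos 2(theta_f - theta_p)` or `1 + P2 cos^2(theta_f -
  theta_p)`, optionally graded across the field), Gaussian PSF, Poisson
  and read noise, with ground-truth sidecars.

## Worked example

Simulate a biased field, detect the bias, correct it, and check the
correction:

```r
library(fourd)

recipe <- fibre_recipe(canvas_px = c(1024, 1024), n_fibres = 52000,
                       length_range_px = c(10, 50), blur_sigma_px = 2.6,
                       downsample = 1, seed = 450)
pol <- polarisation(90, 1, "cos2")     # 50% vertically polarised light
img <- render_image(simulate_field(recipe), pol)

# calibration session: 8 unaligned fields under the same illumination
cal <- smooth_spectrum(mean_spectrum(lapply(1:8, function(k) {
  r <- recipe; r$seed <- 400 + k
  calibration_spectrum(render_image(simulate_field(r), pol))
})), 3)

corrected <- correct_image(img, inverse_operator(cal, dim(img)))

pre  <- alignment_maps(img, 250, 0.5)
post <- alignment_maps(corrected, 250, 0.5)
mean_orientation(as.vector(pre$angle_map))       # 88.5
rayleigh_test(as.vector(pre$angle_map))$p_value  # 1.4e-18
rayleigh_test(as.vector(post$angle_map))$p_value # 0.023
```

Before correction the 49 window angles concentrate at ~88 degrees - the
vertical illumination axis, not the (random) fibres - and the Rayleigh
test rejects uniformity decisively. After FouRD the dominant angle is
gone and uniformity is no longer rejected at the 1% level. The spectrum
itself shows the bias directly: `cal` has `gamma_c ~ 0.10-0.15` across
the structure-bearing rings, and `implied_polarisation_angle(cal)`
recovers the 90-degree illumination axis to within a few degrees.

A one-command version of this workflow (plus TIFF/CSV/JSON artefacts) is
`run_pipeline()`, also exposed as the `end-to-end` subcommand of the CLI
at `inst/cli/fourd.R` alongside `simulate`, `spectrum`, `correct` and
`align`.

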