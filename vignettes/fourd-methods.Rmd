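---
title: "Quantifying and correcting polarisation bias in fibre micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and correcting polarisation bias in fibre micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourd)
```

## The problem

Fluorophores attached to fibrillar structures (collagen labelled through
NHS-ester chemistry, phalloidin-labelled F-actin, and similar) are often
rotationally constrained, with their transition dipoles partially aligned
to the fibre axis. Two consequences matter for quantitative imaging:

* **Polarised emission.** A fibre's emission is partially polarised along
  its own axis, so polarisation-resolved detection channels see the same
  fibre at different brightness depending on its orientation.
* **Photoselection under polarised excitation.** Most laser-based
  microscopes illuminate with partially polarised light. Excitation
  probability follows a cos-squared law in the angle between polarisation
  and absorption dipole, so fibres parallel to the illumination
  polarisation appear brighter than perpendicular ones.

The second effect is insidious: orientation-analysis tools (AFT,
OrientationJ, CytoSpectre) then report sample "alignment" that is actually
a property of the microscope. The bias is essentially invisible by eye and
survives averaging over repeated experiments.

Whether a fluorophore is orientationally constrained at all is governed by
the ratio of its rotational diffusion time to its fluorescence lifetime:
the steady-state anisotropy follows the Perrin relation
`R = R0 / (1 + tau_f / tau_rot)` (`perrin_anisotropy()`). Freely rotating
dye (`tau_rot << tau_f`) is fully depolarised; scaffolded dye retains up
to its fundamental anisotropy.

## Fourier ring anisotropy

Comparing channel brightness per fibre would require segmentation and
perfect channel registration. Both are avoided by working in frequency
space, where position (phase), scale (ring radius) and orientation (ring
angle) separate naturally.

For a polarisation-resolved pair the package forms, per Fourier
coefficient,

    FA = 1 + (|Yv| - |Yh|) / (|Yv| + |Yh|),

after dividing one channel by the detection G factor (`anisotropy_pair()`,
`g_factor` argument; which channel is divided is configurable and only
shifts the profile's constant term, which the moments ignore). Because
only magnitudes enter, a translation of one channel - whose transform
changes only in phase - leaves FA almost unchanged; a regression test
shifts one channel by two pixels and bounds the moment change at 0.02.

Values around a ring of radius `f` form a periodic profile limited to
second order in the angle (single-photon selection rules), summarised by
its weighted second-order circular moments

    gamma_c(f) = sum(FA cos 2theta) / sum(FA),
    gamma_s(f) = sum(FA sin 2theta) / sum(FA),

computed over angles sampled uniformly on the ring by nearest-pixel lookup
(`extract_ring()`, `ring_moments()`, `anisotropy_spectrum()`). Nearest-
pixel sampling (rather than interpolation) keeps the implementation
exactly equal to a brute-force index-lookup oracle, which the tests
exploit; the number of angular samples grows as `2*pi*r` so arc spacing
stays near one pixel. Non-square images use elliptical rings scaled by the
image aspect, indexed along the major axis. The DC ring is always
excluded.

For a single (non-polarisation-resolved) image the same machinery runs on
`FA = |Y|` (`anisotropy_single()`). Its moments then mix intrinsic
alignment with excitation bias - which is exactly what makes the
calibration approach below work.

## Fourier ring depolarisation (FouRD)

In the frequency-space image model the observed transform is the true
transform times a real excitation operator: `Yob = exp(i arg YT) |YT| Yex`,
with `Yex` limited to second order in angle at each ring. A calibration
image of the same structure with **no intrinsic alignment** has an
isotropic `|YT|` in expectation, so its measured moments describe `Yex`
alone.

### The factor two between moments and profile

For a ring profile of the model form `a0 (1 + A cos 2theta)` the measured
cosine moment is `A/2`, not `A` - the standard Fourier-coefficient
relation `gamma_c = a2/a0`. Reconstructing the profile from measured
moments therefore requires doubling them:

    profile(theta) = 1 + 2 gamma_c cos 2theta + 2 gamma_s sin 2theta,

and `inverse_operator()` builds the correction as the reciprocal of this
reconstruction, clamped below by `clamp_floor` (default 0.05) because
noisy moments can drive the reconstructed profile towards zero. Without
the factor two each correction pass would cancel only half the modulation;
with it, multiplying the operator by the profile it was estimated from
returns 1 to within numerical error (a regression test bounds the product
at 1 percent). Rings below `start_radius` (default 2) and DC are left at
exactly 1, and rings beyond the measured spectrum reuse the last moment
pair. Calibration spectra for operator construction should always cover
the full ring range: truncating and extrapolating across the
noise-dominated upper band writes the last structural moment into
frequencies that carry no bias, which visibly biases downstream analysis.

Correction is a direct product in frequency space followed by the inverse
transform (`correct_image()`). The operator is real and positive, so the
phase - all positional structure - is untouched; only relative brightness
across orientations changes. Correcting with an identity operator
conserves total intensity exactly.

### Speckle limits and calibration sessions

The Fourier magnitudes of a random fibre field are approximately Rayleigh
distributed, so per-ring moment estimates from one field carry an
irreducible sampling noise that **does not decrease with fibre density** -
only with ring circumference (image size) and with averaging over fields.
At a 1024-by-1024 image, the smoothed ring-5 standard deviation is around
0.05. The package therefore treats calibration as a session: image several
fields of view, average their spectra (`mean_spectrum()`), and optionally
smooth with a short moving average (`smooth_spectrum()`, the package uses
3 points where smoothing is applied). The round-trip validation below uses
32 fields; noise shrinks with the square root of the count.

A related model limit: per-fibre brightness modulation is only
approximately a frequency-space operator. On a strongly aligned test field
the corrected spectrum approaches, but does not exactly reach, the
unpolarised ground truth (residual per-ring moments of about 0.03-0.04 at
desk scale, independent of calibration quality). When the bias genuinely
is an excitation operator - the model class FouRD assumes, constructed
with `excitation_operator()` - the round trip is exact up to calibration
noise, and the validation suite verifies residuals below 0.02 per ring.

### Patch-wise correction

Where illumination polarisation varies across the field, the image and
calibration are tiled (7 x 7 by default, `patchwise_correct()`) and the
full chain runs per tile. Tiles are non-overlapping and reassembled by
direct placement; the spectral content of the discontinuity this can
create at tile boundaries lives at the lowest tile frequencies, which is
why the
`start_radius` rule doubles as seam mitigation. Raising the start radius
from 2 to 5 with 3-point smoothing removes the seams (the validation
scores the largest boundary step of the Gaussian-smoothed correction
delta, sigma 12 px, and sees a more than five-fold reduction) while
leaving window-level angle distributions statistically indistinguishable
(two-sample Kuiper test).

## Alignment quantification

`patch_orientation()` implements the eccentricity extension of AFT-style
window analysis. The window's mean is subtracted (removing the DC spike),
the centred power spectrum is restricted to the inscribed disc (the
corners of the square spectral support would otherwise dilute the angular
signal), and the central moments mu20, mu02, mu11 of the normalised
spectrum give the closed-form roots

    a, b = (mu20 + mu02)/2 +- sqrt(4 mu11^2 + (mu20 - mu02)^2)/2,

the eccentricity `e = sqrt(1 - b^2/a^2)` and the semimajor-axis angle,
reported in the real-space fibre frame (Fourier structure lies
perpendicular to the fibres). The roots equal the eigenvalues of the
second-moment matrix, which the tests verify against an independent eigen
decomposition. Floating-point can make `b` marginally negative or exceed
`a`; it is clamped to `[0, a]` first. Note that `e` has a positive noise
floor: for a near-isotropic window the eccentricity scales as the square
root of the moment anisotropy, so pure-noise windows sit around 0.2-0.3
rather than 0. Unaligned samples therefore show a small positive mean
eccentricity; the angle, not `e` alone, carries the isotropy evidence.

`alignment_maps()` slides 250-pixel windows (default) with 50 percent
overlap; only complete windows are analysed and no masking or thresholding
is applied. All axial statistics (`circular_variance()`,
`mean_orientation()`, `rayleigh_test()`, `kuiper_test()`) use the
doubled-angle convention for period-180 data.

`orientation_distribution()` is the whole-image counterpart used to
emulate spectral orientation-distribution summaries: Fourier magnitudes
accumulated into 1-degree bins over rings 2 to half-Nyquist by default.
DC and ring 1 are excluded as field-level intensity structure, and the
upper half of rings is excluded as pure detection noise (for the reference
simulation the PSF transfer function is below 10 percent beyond roughly
ring 130 of a 1000-square image). The 1-degree bins carry a 4-fold lattice
count structure which is orthogonal to the doubled-angle moments; the
returned `n_pixels` allows count-normalised flatness checks. This
emulation is deliberately approximate - it reproduces the
orientation-distribution circular variance and mean, not any specific
tool's full spectral decomposition.

## The simulator

`fibre_recipe()` defaults define the reference study conditions: 50,000
fibres, orientations uniform on [0, 180) degrees, lengths uniform on
[50, 250] px, uniformly positioned (overlap allowed) on a 5000-square
canvas, 1000 counts per fibre pixel, Gaussian PSF of sigma 13 px, 5-fold
block-average downsampling (100 nm effective pixels), then Poisson noise
followed by additive Gaussian read noise (mean 20, sd 2). A second recipe
(`matlab_recipe()`) emulates native-pixel acquisition: PSF of 2.7 px FWHM,
constant background of 10 counts, and a fibre brightness (320 counts)
chosen to give roughly 10:1 per-fibre peak SNR under Poisson statistics.

Design choices the recipes do not fix:

* **Rasterisation.** Fibres are 1-pixel-wide anti-aliased lines: unit
  steps along the major axis, bilinearly splatted onto the four
  neighbouring pixels. This keeps deposited flux equal to
  `base_signal * length` at every orientation; nearest-pixel lines would
  alias with angle and themselves bias orientation analysis.
* **Polarisation operators.** `"difference"`:
  `1 + P1 (cos^2 d - sin^2 d) = 1 + P1 cos 2d` with `P1` in [0, 1];
  `"cos2"`: `1 + P2 cos^2 d`, any non-negative `P2`. "50 percent
  vertically polarised light" corresponds to `0.5 + 0.5 cos^2 d`, i.e.
  the `"cos2"` form with strength 1 up to normalisation. The optional
  gradient scales strength linearly with each fibre's origin column.
* **Noise order and clipping.** Poisson then Gaussian, as listed for the
  recipe; the float output is left unclipped, with clipping at zero only
  on explicit 16-bit export.
* **Seeding.** One master seed expands deterministically into independent
  geometry and per-channel noise streams, so a polarisation-resolved pair
  shares geometry but not noise, and identical recipes are bit-identical.
* **Angle convention.** Degrees, 0 = horizontal (+column axis),
  anticlockwise positive, period 180, everywhere in the package.
* **Wrapped ranges.** Angle ranges may start below zero (e.g. `c(-75,
  75)`) and are wrapped modulo 180, so horizontally-centred aligned
  populations are expressible.

What the simulator does not emulate: curved or crosslinked fibres, 3-D
sectioning, depth-dependent blur, detector fixed-pattern noise, or
photobleaching. Passing validation on these phantoms therefore shows the
frequency-space machinery is self-consistent under the stated model; it
does not establish performance on real gels, where fibre curvature and
out-of-focus light shift the structure band and the effective operator.

## Scales used in the validation suite

The two headline statistics (circular variance 0.99 without bias, 0.93
with the 20 percent / 80 degree operator, mean orientation near 169 in
the 90-degree-offset frame) are computed at the full reference scale.
All other image-level scenarios use a scale-preserved desk recipe - a
1024-square single-scale canvas with the same per-image-pixel fibre
statistics as the reference (density 0.05 fibres per px^2, lengths 10-50
px, sigma 2.6 px) - with 32-field calibration sessions for the round-trip
and no-injection scenarios and 8 fields where only qualitative removal is
asserted. The pipeline example in the test suite runs at 384 square with
proportionally fewer fibres.

## Known limitations

* Single-image (calibration) moments are speckle-limited; a single field
  of view cannot estimate the operator to better than ~0.05 per ring at
  desk scale. Average several fields.
* Per-fibre brightness bias is corrected approximately (see above); the
  residual grows with bias strength and intrinsic alignment.
* The emission-side (detection) polarisation of the microscope is not
  corrected - FouRD targets excitation bias estimated from a calibration
  sample.
* Absorption and emission dipoles are treated as parallel; a nonzero
  angle between them adds a depolarisation the model does not represent.
* 2-D only; stacks should be corrected slice by slice.
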