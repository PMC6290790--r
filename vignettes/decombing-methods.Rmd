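---
title: "Comb correction and demosaicking for fibre-bundle imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comb correction and demosaicking for fibre-bundle imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

An imaging fibre bundle relays a scene through thousands of individual
fibrelets separated by opaque cladding. Each fibrelet transmits a single
averaged sample of the scene, and the cladding imprints an irregular dark
lattice — the *comb artifact* — on every frame. When the sensor is a
spectrally resolved detector array (SRDA) carrying an `L x L` mosaic of
spectral filters (here 3 x 3: eight narrow bands plus one broad band), every
raw frame is additionally subsampled by the colour filter array (CFA), and
comb removal interacts with the demosaicking step that reconstructs the
spectral cube.

`decombench` implements the standard correction methods, the metrics that
quantify what each correction preserves or destroys, and a benchmark that
combines the metrics into an application-weighted overall performance score.
Because all of this is validated on synthetic data with known ground truth,
the package also contains a full generative model of the imaging chain.

# The synthetic imaging model

## Comb geometry

`generate_comb()` places fibrelets on a hexagonal lattice with
centre-to-centre pitch `diameter + cladding_gap`, jitters each centre (3% of
the pitch per axis by default) and each radius (5%), and renders each
fibrelet as a disc whose edge is softened by a Gaussian profile of width
`mask_blur_sigma`. The transmission map `C(x, y)` is the sum of the
individual fibrelet masks `C_i`, and the decomposition plus the true
sub-pixel centres are retained as ground truth. Scaling by the magnification
`M` multiplies diameter and pitch together — cores and cladding magnify
alike while the sensor stays fixed, so the fibrelet count scales as `1/M^2`.

Defaults were fixed once, to represent a realistic endoscopic bundle at desk
scale: a 512 px square sensor, fibrelet diameter `D = 8` px and gap 2 px
(pitch 10 px, about 2 900 fibrelets, fill factor ~0.5, and a sampling ratio
`T = L/D = 3/8 < 1` for the 3 x 3 mosaic). The edge softening default of
0.9 px stands for the optical point-spread function and manufacturing
imperfections of real fibrelets; with a much sharper edge the fibrelet
profile becomes a flat-topped cylinder on which the centre-finder's fit
score is nearly constant, which no real calibration frame exhibits. Each
disc's profile is clipped at half the distance to its nearest neighbour, so
the supports of the masks binarised at the fixed threshold 0.1 are disjoint
by construction.

## Image formation

`apply_comb()` implements fibre sampling exactly as stated in the image
model: each fibrelet mask is binarised at 0.1 (strictly greater), the mean
`M_i` of the ideal scene over the binarised support is taken, and the output
is `sum_i C_i M_i`, plus additive Gaussian noise. The noise default is 1% of
the 8-bit dynamic range (sigma = 2.55); the magnitude is a model parameter
because real systems vary widely, and it is deliberately conservative —
single-pixel methods (interpolation) suffer from noise more than averaging
filters do, so a generous noise level avoids flattering the method that
usually wins.

For multispectral scenes, `ms_scene_bands()` scales the comb-sampled scene
by each band's intensity and adds a *stray-light background in the cladding*
(default 10% of the mean scene luminance, spectrally flat). This term is the
model of the "erroneous" cladding spectrum: scattered light in a real bundle
reaches the sensor between fibrelets and differs spectrally from the
transmitted scene. Without it the cladding is exactly black, every
correction method reconstructs the normalised spectrum essentially perfectly
(the spectral error collapses to sampling noise, ~1e-7), and the spectral
accuracy metric cannot distinguish methods; with it, any correction that
mixes cladding pixels into fibrelet spectra pays a measurable, systematic
spectral penalty. It is a diffuse background, not inter-fibrelet crosstalk,
which the model deliberately omits (as it omits vignetting and ray optics).

`apply_cfa()` samples the per-band images with the filter deposition pattern
`P(x, y)` (band index per pixel of the `L x L` super-pixel, anchored at the
image origin with a configurable phase offset), and `simulate_defocus()`
emulates the physical-blurring correction — defocusing the fibre face at
capture time — as a Gaussian blur proportional to the axial displacement,
with the displacement mapped to the common filter-size axis through
`r = |displacement / 0.5 um|`.

## Test targets

`make_target()` builds the three ideal scenes the metrics need: a
multi-element bar target (vertical bars at several line spacings, at least
three bar periods per element), a uniform field, and a bright square on a
darker background (117 / 156 by default). The bar spacings default to 20-80
px, i.e. 2 to 8 fibre pitches: the sampling theorem caps any method's true
resolution near twice the pitch, so finer elements would measure only the
aliasing of the fibre sampling itself, which no correction can undo, while
coarser elements would not fit three periods on the sensor. Targets are
blurred (1 px) to represent target imperfections, and noise is added both
before comb sampling and after it.

# Fibre-centre detection

`find_centres()` implements neighbourhood-based centre detection on a
bright-field calibration frame. A pixel is a candidate if the intensity
range of its `D x D` neighbourhood (`D = 2d + 1`, roughly the fibrelet
diameter) exceeds the user threshold `I_min`; each candidate is scored by
the squared residual between its neighbourhood and the quasi-Gaussian
surface `G = H exp(-l^4 / (2 D^2))` with `H` the candidate's own intensity;
candidates are then accepted greedily in ascending-score order, each
accepted centre excluding all later candidates within one fibre diameter
(strictly `> D`).

Numerical choices that the procedure itself leaves open:

* **Score ties** are broken by raster (row-major) order of the candidate
  coordinates, making the map fully deterministic.
* **Border candidates** whose neighbourhood exits the image are discarded —
  a truncated neighbourhood would bias the fit score.
* **`D` in the exponent** is the full neighbourhood side `2d + 1`, not the
  half-width `d`; the two are easy to confuse and give very different score
  surfaces.
* **Equality rejects**: a candidate exactly `D` away from an accepted centre
  is rejected (the criterion is strict).
* For mosaic (SRDA) calibration frames the image is pre-blurred to wash out
  the CFA pattern before detection; the default width is `L/2` pixels.
* `I_min` must be calibrated to the frame it is applied to: a monochrome
  bright field at intensity ~150 supports `I_min = 50`, while a mosaic
  bright field under broadband light is dominated by the broad band (narrow
  bands carry roughly a tenth of its intensity) and the blurred frame's
  fibrelet/cladding contrast is ~28, hence the multispectral default of 12.

The score scales with `H^2`, so dim structures near the bundle's outer edge
can outscore genuine centres; on frames where the bundle fills the sensor
(the normal calibration situation) interior cladding cannot do this because
its neighbourhoods always contain bright fibrelets.

# Decombing methods

All filter methods share one size parameter `r` (valid range `1 < r < 50`
pixels):

* `gaussian_decomb()` — 2-D Gaussian convolution with standard deviation
  `r` (separable, mirror-symmetric boundary).
* `median_decomb()` — sliding median over a `2r x 2r` window. The even
  window has no centre pixel; it is anchored so its top-left `r x r`
  quadrant covers the output pixel, the median of the even sample is the
  mean of the two central order statistics, and borders are mirrored.
* `fourier_decomb()` — discrete Fourier transform, removal of all
  frequencies above `f0 = 1/(2r)` cycles/pixel (so `r` is the smallest
  surviving feature size, by Nyquist), inverse transform, real part. The
  "crop" is radial by default for isotropy; a square support is available
  as an option since the wording admits either reading.
* `interpolation_decomb()` — reads one pixel per fibrelet at the detected
  centres and rebuilds the image by piecewise-linear interpolation over the
  scattered centres. The triangulation is Delaunay (Bowyer-Watson,
  implemented in the package with a deterministic 1e-7 px symbolic
  perturbation to break grid ties); pixels outside the convex hull take the
  nearest centre's value and are flagged in a validity-mask attribute. An
  optional small-disc mean per centre exists but is off by default — the
  method's character (and its noise sensitivity) comes precisely from using
  a single pixel per fibrelet.
* `physical` — the correction happened optically at capture; in software it
  is the identity on the pre-blurred frame.

`r` is stated in pixels throughout: although introduced as a dimensionless
parameter unifying the methods, every use fixes the pixel as its unit.

# Demosaicking

`simple_demosaick()` splits the raw mosaic into `L^2` sparse band images and
fills each band's regular lattice by bilinear interpolation (edges clamp to
the outermost defined sites). Filtering must happen **after** this split:
smoothing the raw mosaic first would average neighbouring pixels that carry
different spectral filters and corrupt every recorded spectrum (the package
tests this ordering by measuring the spectral error of both orders).

`centre_based_demosaick()` performs decombing and demosaicking
simultaneously: at each fibre centre, band `k` is read from the
Euclidean-nearest raw pixel whose pattern index is `k` — the centre pixel
supplies its own band — which is well-defined whenever one super-pixel fits
inside a fibrelet, i.e. `T = L/D < 1` (checked, and refused otherwise).
Equidistant neighbours, possible for even `L`, are averaged (the
deterministic one of the two sanctioned tie rules). One interpolation table
is then built from the shared centre map and applied to all bands
(`interpolate_centre_spectra()`): in every band and every frame the
interpolation runs between the same centre points, so the table is computed
once.

# Performance metrics

* **Resolution** `R`: Michelson contrast `(I_max - I_min)/(I_max + I_min)`
  per bar element, a smoothing spline of contrast versus line spacing, and
  the spacing at the 5% crossing (5% rather than 1% to stay clear of noise).
  The element levels are estimated from the row-averaged profile over the
  central thirds of bars and spaces — averaging over many bars cancels
  residual comb ripple — and the contrast is kept signed so aliased elements
  fluctuate around zero instead of accumulating spurious positive contrast.
  The spline uses generalised cross-validation with a fixed-stiffness
  fallback. If contrast exceeds 1% at no more than 3 distinct spacings no
  spline is fitted and `R` is undefined; score normalisation then assigns
  the worst score. If the fitted contrast never falls below 5%, resolution
  is limited by the target and the smallest spacing is reported. For cubes,
  `R` is averaged over the bands.
* **Smoothness** `sigma`: population standard deviation of the uniform-field
  frame (band-averaged for cubes). The benchmark evaluates it on the full
  frame: the full-frame variance of a linear low-pass output is
  non-increasing in the filter size (Parseval), which makes the expected
  monotone behaviour a property of the method rather than of a region
  choice.
* **Signal** `S`: mean intensity in a region of interest inside the bright
  region; for cubes, averaged over the bands overlapping the emission of a
  far-red fluorophore (665 nm, 714 nm, broad band).
* **Speed** `t`: median wall-clock seconds per corrected frame. Reported,
  never scored — speed can be optimised independently.
* **Accuracy of spectral reconstruction** `Q`: the cube's per-band spatial
  means, normalised to unit sum, compared with the predicted recorded
  spectrum `E^k = sum_lambda G(lambda) R^k(lambda)` (also unit-normalised)
  by the sum of squared differences. Averaging over pixels *before*
  normalising keeps non-smoothness out of `Q`, which the smoothness metric
  already measures.

Scores are min-max normalised across the whole comparison set of one run
(`S_res = 1 - (R - R_min)/(R_max - R_min)` and so on; signal has the
opposite polarity), so 1 marks the best and 0 the worst method *of that
run* — scores from different runs are not comparable, and the run manifest
records the extrema used.

# Overall performance and the benchmark

`overall_performance()` is the weighted sum
`OP = w_res S_res + w_smooth S_smooth + w_signal S_signal + w_ASR S_ASR`
over the application weight simplex (monochrome imaging fixes `w_ASR = 0`).
`sweep_weights()` evaluates all methods at every weighting on a regular
simplex grid (step 0.01 for three active weights, 0.05 for four) and records
the winner; exact ties go to the fixed order interpolation, Fourier,
Gaussian, median, physical, then to the smaller `r`. The grid step only
samples the map — a winner at a given weighting is independent of the step,
which the tests assert by refining the grid.

`run_benchmark()` drives the whole pipeline at the reference conditions: 512 px
frames, the default comb, one centre map built from a bright-field
calibration frame and reused everywhere, every method at
`r in {2, 3, 5, 8, 12, 18, 25, 35, 48}` (monochrome) or `{2, 5, 10, 25}`
(multispectral), metrics, normalisation, sweep. On one CPU the monochrome
run takes roughly two minutes and the multispectral run several minutes,
dominated by the exact sliding median at large windows. In multispectral
mode the spatial fixtures and the calibration frame use spectrally flat
(broadband) illumination, while the spectral-accuracy fixture uses a
narrow-band LED source with fully known `G`, `R^k` and hence `E^k`
(`default_calibration()`); this mirrors the practice of measuring resolution
under broadband light but spectral fidelity under a known source.

# What the synthetic benchmark does and does not show

The generator reproduces the features the corrections interact with:
irregular fibrelet placement and size, opaque cladding with stray
background light, per-fibrelet scene averaging, additive sensor noise, CFA
subsampling, and defocus blur. It does **not** model inter-fibrelet
crosstalk, vignetting, wavelength-dependent fibre transmission, nonlinear
sensor response, or real optics; and its stray-light spectrum is flat,
whereas a real bundle's is not. Consequently the benchmark's *orderings*
(which method wins where, how trade-offs move with `r`) transfer to real
systems insofar as these mechanisms dominate, but the *absolute* metric
values do not: resolution here is bounded by the 20 px smallest bar
spacing, and the spectral error magnitudes scale directly with the assumed
stray-light fraction.

Typical behaviour at the defaults: interpolation wins most of the weight
simplex, including the resolution and signal corners and (in multispectral
mode, by two orders of magnitude in `Q`) the spectral-accuracy corner;
Gaussian filtering at large `r` wins when smoothness is the sole priority;
Fourier filtering sits between; the median filter's spectral accuracy is
the worst of the filters, because the sparse "true" fibrelet pixels lose
the vote against the more numerous cladding pixels inside its window.

# Known limitations

* The Bowyer-Watson triangulation is quadratic-time in the centre count;
  it is comfortable at 10^4 centres but not built for 10^6.
* The exact even-window sliding median dominates benchmark runtime at
  `r >= 25`; an approximate histogram median would be faster but would
  break the exactness the tests rely on.
* Resolution estimates inherit the smoothing spline's behaviour near the
  target's smallest spacing; the benchmark treats differences there at the
  percent level of the spacing range as estimator jitter.
* Centre detection assumes the bundle fills the calibration frame; on
  frames with a dark margin the `H^2` scaling of the fit score can accept
  spurious dim candidates near the bundle edge (they are excluded from
  nothing but flagged by their high scores).
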