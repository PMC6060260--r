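---
title: "Presynaptic calcium imaging analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presynaptic calcium imaging analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`boutonca` analyses two-channel fluorescence time-lapse recordings of
presynaptic boutons expressing a green genetically encoded calcium
indicator together with a calcium-independent red reference protein. This
vignette describes the models behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## Data model

An acquisition alternates the excitation wavelength frame by frame, so the
raw stack interleaves the two channels; `deinterleave()` separates them.
Within one channel, sample $i$ lies at $i \cdot \Delta t$ from that
channel's first frame. The half-frame offset between the channels is
ignored: it is an order of magnitude below every time constant fitted
downstream. Pixel coordinates are 0-based `(row, col)`, row-major, with
pixel centers at integer coordinates. Metadata (frame interval, channel
order, stimulus protocol) live in a YAML sidecar rather than TIFF tags so
that any TIFF dialect can be read. The channel order of the interleave is
configuration (default green-first), since alternating-excitation hardware
does not dictate which wavelength leads.

## Photobleaching

Continuous illumination bleaches the indicator. Bleaching is measured on
control acquisitions taken at zero stimulus intensity and modeled as

$$B(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c, \qquad B(0) = 1,$$

with $\tau_1 \le \tau_2$ by convention. `fit_bleach_model()` fits the
model by multi-start nonlinear least squares (six log-spaced $\tau$
initializations spanning the trace duration, Levenberg–Marquardt steps,
non-negativity bounds on amplitudes). If no double-exponential start
converges, a single exponential is fitted instead and the result records
this. A trace whose coefficient of variation is below $10^{-9}$ returns
the constant model directly.

Correction is **divisive** — traces are divided by $B(t)$ — not
subtractive. Bleaching removes a fraction of the fluorophores and
therefore scales emitted fluorescence multiplicatively; dividing restores
the unbleached scale exactly when the model is exact, which is also what
the exact-cancellation tests assert. $B(t) \le 0$ at any sample is a
domain error rather than silent clipping.

## F/F~0~ normalization

$F_0$ is the mean of all samples strictly before stimulus onset, with no
frame exclusion. Values become $F/F_0$ and times are re-referenced so the
last pre-stimulus sample is $t = 0$. By construction the pre-onset mean of
every normalized trace is 1; this is asserted to $10^{-9}$ over a
thousand random traces. Background subtraction (from a neighboring
background ROI, or a scalar level measured in wild-type tissue) is
pointwise and never clips negative values, keeping downstream estimators
unbiased.

## Segmentation

Boutons appear as diffraction-limited bright puncta. Detection operates on
the temporal average of the stack (averaging ~100 frames suppresses pixel
noise by ~10×) and runs:

1. negated discrete Laplacian, kernel $[[0,1,0],[1,-4,1],[0,1,0]]$, sign
   flipped so bright blobs respond positively; borders are
   replicate-padded;
2. threshold at `k_sd` × SD of all Laplacian pixel values (default
   `k_sd = 3`);
3. connected components (8-connectivity default), discarding components
   outside `[min_area_px, max_area_px]` (defaults 2 and 100 px);
4. one punctum ROI per component, centered at its maximum-intensity pixel,
   ties broken toward the smallest row-major index.

The Laplacian discretization, the SD multiple, the connectivity and the
area limits are all configuration: none is dictated by the measurement
itself, and the defaults are conventional values for spot detection at
this spot size. Output ordering is deterministic (sorted by center), and a
constant image returns an empty list rather than an error. Because the
Laplacian annihilates constants, detection is invariant to a constant
intensity offset; raising `k_sd` can only shrink the detection set.

Fixed 3×3 ROIs (`make_fixed_rois()`) circumscribe single boutons at
stated centers, cropped at image borders. Background ROIs are placed at
`offset_px` (default 4 px) from each punctum center in the first of the
eight compass directions — base order N, NE, E, SE, S, SW, W, NW, shuffled
by the seed — whose 3×3 window stays in-image and overlaps no punctum.
Diagonal offsets are rounded to the pixel grid, so their Euclidean
distance matches `offset_px` only to within rounding. Puncta with no
qualifying direction are skipped and reported, not errored.

## Responder classification

Each normalized trace, z-scored over time, is a feature vector; the full
trace is used rather than summary statistics because the response shape —
not just its amplitude — separates responders. Agglomerative clustering
(Ward linkage on Euclidean distances) is cut into two clusters, and the
cluster with the higher mean $F/F_0$ inside the response window
`[onset, onset + stim_window_s]` is the responder candidate. A guard then
replaces the manual verification step of interactive workflows, which is
not reproducible in code: if the candidate cluster's mean trace peaks less
than `min_response` above baseline, the whole set is declared
non-responding. `min_response` defaults to twice the pooled SD of
pre-onset $F/F_0$ values. The reported proportion is exactly
`responders / total`. Permuting the input permutes the labels identically.

## Kinetics

Per normalized trace the package measures, on the raw samples without
smoothing: peak ($\max F/F_0 - 1$ after onset, ties to the earliest
sample), time to peak from onset, initial slope (least-squares slope over
the first three post-onset samples by default; the window is
configuration), and the 2-s area under $F/F_0 - 1$ by trapezoidal
integration with linear interpolation at the window ends.

Post-peak decay is fitted as $y(t) = 1 + \sum_i a_i e^{-(t -
t_{peak})/\tau_i}$ with one and with two components, and the model is
selected by corrected AIC with the per-point variance floored at
$(10^{-8} \cdot \mathrm{peak})^2$ so numerically perfect fits cannot
produce unbounded likelihoods. The *fast* $\tau$ is the single time
constant or the faster of the two. An identifiability guard collapses a
nominally better double fit to single when the two time constants differ
by less than 1.5×, when a component carries under 5% of the total
amplitude, or when the fast time constant falls below three sampling
intervals — in each case the second component is not a resolvable decay
process at the given sampling, only a re-parameterization of noise.

Stimulus–response relations are fitted with a 4-parameter logistic
$y = base + (top - base) / (1 + e^{(x_{50} - x)/rate})$ (multi-start over
$x_{50}$ and rate), and sub-saturating ranges with ordinary least squares
restricted to $x < x_{max}$, reporting slope, intercept and Pearson $r$.

## Flat-field correction, stitching, ratio images

Mosaics of a whole section are built from overlapping tiles under a shared
illumination pattern. The flat-field reference is the pixelwise tile
average (edge tiles excluded by the caller), smoothed with a Gaussian
filter of kernel width 121 px and normalized to mean 1 so correction
preserves the global intensity scale. Whether "a kernel of 121 pixels"
denotes the support or the standard deviation is ambiguous; the package
takes it as the full support with $\sigma = 121/6$ (the conventional
6-sigma truncation), and both are configurable. The blur uses separable
convolution with replicate padding — FFT-based filtering with circular
boundaries would wrap the dark vignette corners around the image edge and
bias the reference.

Tiles are divided by the reference and placed on the known grid (stride =
tile size × (1 − overlap)); overlapping pixels are blended linearly with
distance-to-edge weights, so exact crops reassemble the truth image
exactly. Feature-based tile registration is deliberately out of scope:
the generator emits exact offsets, so placement, not registration, is the
step under test.

Ratio images are $(G - bg_G)/(R - bg_R)$ with background levels measured
from wild-type tissue; pixels with non-positive denominators are masked
`NA`, never infinite, and the mask size is reported. Because both channels
share the illumination and the correction, the ratio is invariant to a
global illumination change.

Colocalization is the sample Pearson correlation of two intensity
profiles along a line, with a two-sided p value from the t transform on
$n - 2$ degrees of freedom.

## The synthetic-data generator

The generator is the package's stand-in for slice recordings, which are
not deposited; every artifact is a pure function of (parameters, seed).
It emulates:

* boutons as 2-D Gaussian spots ($\sigma$ default 1.5 px) rendered by
  analytic integration of the profile over pixel areas, so sub-pixel
  centers shift centroids measurably;
* stimulus-train green transients: each stimulus adds `amp_per_stim`
  (F/F~0~ units) decaying as $e^{-\Delta t/\tau}$, with the summed
  transient clipped at `saturation_cap` — a hard cap chosen to reproduce
  the plateau seen above ~20 stimuli without asserting a functional form
  the data do not constrain;
* a calcium-independent red channel (no stimulus-locked component, which
  the generator's invariant test verifies by regression);
* multiplicative double-exponential bleaching per channel, red defaulting
  to 30% of the green amplitudes;
* Poisson (via `photon_gain`) then additive Gaussian noise — camera noise
  is otherwise uncharacterized, so this standard two-stage model is a
  choice, not a calibrated claim;
* an autofluorescent background: uniform, or a Gaussian-smoothed random
  field with 10% relative SD when a correlation length is given;
* vignetted overlapping tile grids (radial Gaussian falloff to
  `1 - strength` at tile corners, shared across tiles) and bivariate
  Gaussian line-profile pairs with a target correlation.

The default single-bouton regime mirrors the emulated recordings: 64 ×
512 px frames at 98 ms intervals, trains of 10–20 stimuli at 10–20 Hz.
Transient amplitude per stimulus has no published value for this
preparation; the defaults (0.05–0.06 F/F~0~ per stimulus, $\tau$ = 1 s)
are free parameters chosen to give single-trial peaks around 0.4–0.5
F/F~0~, and recovery results should be read as properties of the
algorithms under the stated signal-to-noise ratios, not as claims about
tissue. The generator does not model optics beyond a Gaussian spot, tissue
movement, photoswitching, or spatially varying bleach — so passing tests
demonstrate correctness of the analysis under the stated statistical
structure, not robustness to those real-world artifacts.

## Validation problem sizes

The packaged benchmarks (also run by `scripts/acceptance.R`) use: 200
bleach-control samples over a 50-s window, noiseless and at 2% noise over
20 seeds; 1,000 random traces for the F/F~0~ contract; twenty 64×512
fields of 40 boutons (spot amplitude 8× frame noise SD, spacing ≥ 6 px,
100-frame averages) for segmentation; twenty sets of 100 traces (30%
responders, peak SNR 20) plus twenty pure-noise sets for classification;
$\tau \in \{0.2, 0.5, 1, 2\}$ s × 20 seeds at SNR 10 for decay recovery;
a 3×3 grid of ~390-px tiles (large relative to the 121-px kernel, as for
the emulated sCMOS camera) for flat-fielding; and two full pipeline runs
for determinism. These sizes were chosen so the whole suite completes in
well under a minute per stage on a laptop while keeping Monte-Carlo
standard errors small against the tolerances tested.

## Known limitations

* The bleach-control window must keep the control well above the noise
  floor; controls clipped at zero violate the fit's positivity
  precondition and error out rather than being silently repaired.
* The classifier assumes a common time base and a two-cluster structure;
  graded response populations are reported only as responder proportion.
* Placement-only stitching cannot correct stage-position errors.
* Absolute calcium calibration from the green/red ratio requires
  instrument constants the package does not model; ratios are reported in
  arbitrary units.
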