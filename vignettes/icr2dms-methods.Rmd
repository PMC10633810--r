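---
title: "Two-dimensional FT-ICR MS with quadrupolar detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional FT-ICR MS with quadrupolar detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icr2dms)
```

## The measurement this package models

Two-dimensional mass spectrometry (2D MS) on an FT-ICR instrument is a
data-independent tandem-MS mode: instead of isolating one precursor at a
time, all precursor ions are radius-modulated in the ICR cell with an
encoding pulse--delay--pulse sequence whose delay `t1` is incremented scan
by scan. Because a radius-dependent fragmentation method (here electron
capture dissociation, ECD) follows the encoding, each precursor's fragment
yields oscillate with the precursor's own cyclotron frequency as a function
of `t1`. A Fourier transform along `t1` (on top of the usual transform
along the detection time `t2`) therefore spreads fragments vertically by
the frequency of the precursor that produced them: the 2D spectrum
correlates every fragment (horizontal m/z) with its precursor (vertical
m/z) without any isolation step.

Under quadrupolar (two-omega) detection, the four-plate ICR cell detects
ion signals at twice the reduced cyclotron frequency. Two consequences
matter for processing and are encoded in `ioncal`:

* the frequency-to-m/z conversion coefficients of the horizontal
  (fragment) axis are doubled relative to the vertical axis, and
* for a given transient length the resolving power doubles (tested by a
  matched-simulation property in the suite).

### Calibration model

Both axes use the quadratic law `f = a/mz + b/mz^2` with the one-term
ideal coefficient `a = h * 1.535611e7 * B` Hz Th (harmonic `h`, field `B`
in tesla) and `b = 0` by default; no published calibration constants are
assumed, and this one-term law reproduces every printed frequency of a
12 T instrument within 0.05% (166.67 kHz encoding bandwidth for a 3 us
increment; 61.4--937.5 kHz fundamental excitation range; 122.8 kHz
two-omega frequency at m/z 3000).

The vertical (precursor) dimension is modeled at the *fundamental*
frequency: the modulation frequency of a precursor is
`f_ICR(mz) - f_min`, with `f_min` the digital modulation floor at the
fundamental frequency of the highest excited m/z. The instrument
literature describes the floor as doubled under two-omega detection, but
the printed minimum modulated precursor m/z (808.1 at 12 T with a 3 us
increment) is arithmetically consistent only with the fundamental-frequency
floor (61.4 kHz) plus the 166.67 kHz encoding Nyquist bandwidth; the
implementation follows the numbers. `precursor_mz_range()` reproduces
808.1 within 0.03%.

Axis bins are half-open and 0-based in frequency: bin `k` of an `N`-point
magnitude spectrum over bandwidth `W` sits at `k W / N`, converted to m/z
per dimension (the horizontal DC bin, which has no m/z, is dropped).

## The forward model (`sim2d`)

`simulate_transient2d()` generates the `n_t1 x n_t2` real transient from a
list of precursor channels. For encoding step `k` and modulation phase
`phi = 2 pi f_mod k dt1`:

* the **precursor's** detected amplitude follows the nonsinusoidal
  waveform `cos(phi) + sum_j w_j cos((j+1) phi)` scaled by its
  unfragmented fraction; the overtone weights `w_j` (default 0.2, 0.05)
  produce the harmonic peaks of the autocorrelation line seen in real 2D
  spectra;
* **fragments and electron-capture products** are anti-modulated through a
  Gaussian on-axis overlap `exp(-(r/r0)^2)` with normalized radius
  `|cos(phi/2)|`: ions return to the cell axis once per modulation period,
  where radius-dependent ECD is most efficient. The exact efficiency
  profile of a real cell is not published; any smooth decreasing overlap
  yields the required anti-phase modulation, and the Gaussian width is a
  model parameter, not an instrument claim. The default `r0 = 0.8` was
  calibrated once against the reported intensity scale of modulation
  harmonics (second harmonic about 15--20% of the fundamental); much
  smaller radii turn the overlap into a narrow pulse train whose harmonic
  comb would dominate the vertical dimension.
* every species contributes a decaying cosine along `t2` at its
  detection-harmonic frequency (decay constant = transient duration, a
  mild apodization-like damping); under two-omega detection a
  `leakage_1w` fraction adds a duplicate cosine at half the frequency,
  which is what produces the half-slope subharmonic image of the
  autocorrelation line;
* each `t1` row is scaled by an independent factor
  `1 + cv * N(0,1)` (scintillation, i.e. scan-to-scan ion-number
  fluctuation, which becomes vertical streaks), and white thermal noise is
  added everywhere. Everything is reproducible from one integer seed.

When a channel carries an isotope pattern, each precursor isotopologue is
modulated at its own frequency, and fragment isotopologues are drawn by
binomial transfer of the precursor's extra neutrons (transfer probability
= mass fraction of the fragment). This reproduces the practical reason for
summing adjacent fragment scans: a single scan samples only part of the
precursor envelope and distorts fragment isotope ratios.

### The acetylated-ubiquitin scenario

`ubiquitin_fixture()` builds the full study scenario: charge states 7--10+
of ubiquitin carrying 4--6 acetylations on the eight candidate sites (M1,
K6, K11, K27, K29, K33, K48, K63). The user supplies per-site occupancy
probabilities; proteoform abundances follow the Poisson-binomial total
count distribution, and each c/z fragment channel's yield is the *exact*
conditional probability of carrying `j` acetylations given the
proteoform's total -- so the generator's ground truth is analytic, and
uniform occupancies reduce to a hypergeometric span distribution that the
tests check against closed form. The charge-state weights shift down by
0.7 charges per added acetylation, emulating charge reduction by lysine
neutralization. The fragment ladder defaults to index pairs bracketing
every candidate site, so site-resolved occupancy differencing is possible.

What the generator deliberately does **not** emulate: space-charge and
cell-geometry frequency shifts, magnetron/axial motion, phase-cycled
averaging, vendor raw formats, and the full 1M x 4096 production array
sizes. Tests passing on this generator show the processing and
quantification logic is correct under the method's signal model; they do
not certify performance on real transients.

## Processing (`proc2d`)

The chain mirrors standard magnitude-mode 2D processing: Kaiser
apodization along `t2` (shape `beta = 6` by default; 0 is rectangular),
zero filling once (default), FFT along `t2`, optional low-rank denoising
of the `t1` interferograms, per-interferogram mean removal (the
unmodulated background, which otherwise fills vertical bin 0), FFT along
`t1`, magnitude, and calibrated axes per dimension.

**Denoising.** `sane_denoise()` implements the low-rank random-projection
family used for FT-MS interferograms: Hankel embedding (window
`min(n/2, 512)`), a randomized range finder with 8 oversampling directions
and one re-orthogonalized power iteration, truncation to the requested
rank (default 30), and anti-diagonal averaging. The projector's seed is an
explicit argument, so processing is deterministic. A practical limitation
surfaced by simulation: with very short encodings (window of ~128 points)
a rank-30 truncation retains too much of the noise subspace to help; the
rank-30 default assumes windows at least an order of magnitude above the
rank, which production-size interferograms satisfy.

**Peak picking.** 2D local maxima over a 3x3 neighborhood, SNR against a
per-row robust noise estimate (1.4826 x MAD, re-estimated after masking
picked peaks -- the robust two-pass estimator standard in FT-MS practice;
the method papers do not define their SNR estimator), and centroid
refinement by one-dimensional parabolic interpolation per dimension. With
one extra zero-fill the refined horizontal centroids of clean peaks are
within 2 ppm; tie-breaks at plateau maxima keep the lowest-index bin.

## Extraction (`extract2d`)

The autocorrelation line samples each vertical bin at the horizontal
position equal to its precursor m/z (linear interpolation between
horizontal bins; out-of-range samples are zeroed and counted in the scan
metadata). Fragment scans sum an odd number of adjacent rows (default 5,
the number used in the study's worked example) centered on the precursor;
precursor scans return the vertical column nearest a fragment m/z;
electron-capture lines sample along `mz_prec = ((n-1)/n) mz_frag`.
Artifact labeling tests membership of the known line equations with a
tolerance of one vertical bin plus the vertical image of a 20 ppm
fragment-dimension error (the vertical resolution is orders of magnitude
below the horizontal one, so the vertical bin dominates).

## Quantification (`quantify`)

Scan peaks are matched to a theoretical c/z/y library within a ppm
tolerance (default 5 ppm), ties broken by smaller absolute error then
lower modification count, with an optional isotope-envelope cosine gate
(threshold 0.9). Cleavage coverage is the percentage of inter-residue
bonds evidenced by at least one terminal fragment, pooled across charge
states for union coverage.

**Occupancy profiles.** For one proteoform (total count `n`) and one
series, the intensity-weighted mean modification count
`A(i) = sum_j j I(i,j) / sum_j I(i,j)` over the fragment ladder is made
nondecreasing by weighted pool-adjacent-violators regression and anchored
at the intact protein (`A = n` for the complete chain). The per-site rate
is the increase of `A` across each candidate site; an increase spanning
several sites with no intervening ladder coverage is split uniformly among
them (the same ambiguity the real data shows between K27/K29/K33), and
spans with no candidate site carry their increase forward. Rates therefore
sum to `n` by construction. "Rate" here is defined as the occupancy
fraction of a site within a proteoform, so a fully localized single
acetylation gives a unit step.

**Average charge.** FT-ICR peak intensity is proportional to abundance
times charge, so the abundance-weighted mean charge of an intensity table
`I(z, n)` is computed as `<z>(n) = sum_z I / sum_z (I/z)`. This is the
algebraic form implied by the stated proportionality; it is
scale-invariant and reduces to `z` for a single charge state.

## Validation strategy and problem sizes

The package separates two questions and tests them independently:

1. *Does the 2D measurement chain locate and weigh species correctly?*
   Tested on small simulated arrays (64--512 encoding steps, 1024--8192
   transient points): calibration round-trips, bin-exact FT placement,
   half-bin vertical / 2 ppm horizontal chain accuracy on a noise-free
   species, capture-line and subharmonic geometry (slope 0.50 +/- 0.02 on
   a 512 x 4096 simulation), resolving-power doubling between harmonics
   (ratio 2.0 +/- 0.1), and denoising gains on a noisy multi-proteoform
   fixture.
2. *Does the quantification invert fragment intensities into site
   occupancies?* Tested by feeding the fixture's analytic channel table
   (with small multiplicative noise) through the matching and profiling
   code: per-site recovery within +/-0.1, exact ranking recovery, and
   c-/z-side agreement. Re-measuring every one of the ~1500 fragment
   lines from a single 2D array would need production-size spectra, which
   the test problem sizes deliberately avoid; the scan-level fidelity is
   already covered by (1).

Numerical conventions worth knowing: monoisotopic masses derive from one
isotope table (so the acetylation delta is the composition-derived
42.0105647 Da); z ions are z-dot radicals (`y - 16.018724` Da); the proton
is 1.00727646 Da and electron masses are neglected in fragment m/z;
isotopologue aggregation is by extra-neutron count with abundance-weighted
mean masses, pruned at 1e-4 relative abundance by default. The printed
reference value for ubiquitin's c3 ion sits 2.4 ppm above the standard
c-ion theoretical mass; comparisons against printed fragment values use
5 ppm.

## A short worked example

```{r, eval = FALSE}
fx <- ubiquitin_fixture(c(0.7, 0.8, 0.35, 0.4, 0.45, 0.6, 0.9, 0.95),
                        charge_states = 8L, n_mods = 4:5)
tr <- simulate_transient2d(fx$config, fx$channels,
                           noise_model(thermal_sigma = 0.02), seed = 1)
sp <- ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
peaks <- flag_artifacts(peak_pick_2d(sp, snr_threshold = 5), sp)
scan <- fragment_scan(sp, precursor_mz(protein_sequence(ubiquitin_sequence()),
                                       acetyl_spec(), 5, 8), 5)
```

`run_pipeline()` chains the same stages from a JSON configuration and
writes serialized datasets, CSV scan/peak/assignment tables and a JSON
summary; the installed `exec/icr2dms` script exposes it on the command
line.

## Known limitations

* The modulation waveform and overlap profile are documented models, not
  instrument measurements; absolute intensities are arbitrary units.
* The quadratic calibration term defaults to zero; real spectra need a
  fitted `coeff_b` per dimension.
* Fragment chemistry covers a/b/c/y/z (z-dot) with a variable
  modification; neutral-loss series and internal fragments are out of
  scope.
* Vertical-dimension accuracy is bin-limited; no super-resolution model
  of the precursor dimension is attempted.
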