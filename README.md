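# icr2dms — two-dimensional FT-ICR MS with quadrupolar detection

`icr2dms` is an R toolkit for **two-dimensional Fourier transform ion
cyclotron resonance mass spectrometry (2D FT-ICR MS)** acquired with
**quadrupolar (2ω) detection**, aimed at analysts and method developers in
top-down proteomics who want to simulate, process and interpret 2D ECD
spectra — in particular for label-free quantification of variable
modifications such as lysine/N-terminal acetylation of intact proteins.

2D MS correlates precursors and fragments *without ion isolation*: an
encoding pulse–delay–pulse sequence modulates every precursor's cell
radius at its reduced cyclotron frequency `f_ICR = a/(m/z)` before
radius-dependent ECD fragmentation, so fragment yields oscillate with
their precursor's frequency as the encoding delay `t₁` is incremented. A
2D Fourier transform of the `t₁ × t₂` transient yields a spectrum whose
horizontal axis is fragment m/z, vertical axis precursor m/z. Under
quadrupolar detection the horizontal calibration coefficients are doubled
(`f = h·1.535611×10⁷·B/(m/z)` at harmonic `h`), the resolving power
doubles for a given transient length, and a 1ω-leakage subharmonic image
of the autocorrelation line appears at slope 1/2. The vertical dimension
covers modulation frequencies `f_ICR − f_min` up to the encoding Nyquist
bandwidth `1/(2Δt₁)`.

The package provides:

* `ioncal` — quadratic frequency↔m/z laws per dimension, harmonic
  scaling, encoding-bandwidth and precursor-range arithmetic;
* `sim2d` — a forward model of 2D transients (nonsinusoidal modulation,
  ECD fragment and electron-capture channels, scintillation noise, 1ω
  leakage) plus `ubiquitin_fixture()`, a ground-truthed acetylated-
  ubiquitin scenario;
* `proc2d` — Kaiser apodization, zero filling, calibrated 2D magnitude
  FT, SANE-style low-rank Hankel denoising, 2D peak picking;
* `extract2d` — autocorrelation line, fragment/precursor scans,
  electron-capture lines (slope `(n−1)/n`), SNR, artifact labeling;
* `proteoform` / `quantify` — c/z/y fragment libraries with variable
  acetylation, isotope patterns, ppm matching with envelope gating,
  cleavage coverage, per-site acetylation-rate profiles and
  abundance-weighted average charge `⟨z⟩(n) = ΣI / Σ(I/z)`.

## Worked example

```r
library(icr2dms)

law1 <- calibration_law(12, harmonic = 1L)          # 12 T, fundamental
cfg  <- instrument_config(12, 3000, 196.51, 3e-6, 4096L, 2^20, 0.559, 2L)
mz_to_freq(3000, law1) / 1e3                        # 61.4  kHz (1ω)
mz_to_freq(3000, scale_to_harmonic(law1, 2)) / 1e3  # 122.8 kHz (2ω)
precursor_mz_range(cfg)                             # 807.9 – 3000

ubi <- protein_sequence(ubiquitin_sequence())
fragment_mz(ubi, "c", 3, 1)             # 390.21695 (c3, 1+)
fragment_mz(ubi, "c", 3, 1, n_mods = 1) # 432.22752 (c3 + acetyl)

## simulate an acetylated-ubiquitin 2D measurement and process it
fx <- ubiquitin_fixture(c(0.7, 0.8, 0.35, 0.4, 0.45, 0.6, 0.9, 0.95),
                        charge_states = 8L, n_mods = 4:5,
                        config = instrument_config(12, 3000, 250, 3e-6,
                                                   256, 2048, 2048/3.2e6, 2))
tr <- simulate_transient2d(fx$config, fx$channels,
                           noise_model(thermal_sigma = 0.02), seed = 1)
sp <- ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
sp
#> <spectrum2d> 129 x 2048; precursor m/z 807.9-3000.0, fragment m/z 230.3-471739.7
pk <- flag_artifacts(peak_pick_2d(sp, snr_threshold = 8), sp)
head(pk[, c("mz_prec", "mz_frag", "snr", "label")], 3)
#>   mz_prec mz_frag       snr           label
#> 1 1095.52 1096.05 11888.0   autocorrelation
#> 2 1016.18 1096.67  4279.9   scintillation_streak
#> 3 1095.49 1253.10   578.0   capture_line(8)
```

The strongest peak is the `[M+8H+5Ac]⁸⁺` species on the autocorrelation
diagonal (precursor m/z ≈ fragment m/z ≈ 1095.6); the `capture_line(8)`
peak at (1253.1, 1095.5) is its singly charge-reduced electron-capture
product on the 7/8-slope line. Fragment scans
(`fragment_scan(sp, mz, 5)`), library matching (`match_fragments`) and
`acetylation_profile()` then turn assigned c/z ladders into per-site
acetylation rates that sum to the proteoform's modification count; on
ground-truthed simulations the injected site occupancies are recovered
within ±0.1 with exact site ranking.

`run_pipeline(config, out_dir)` chains
simulate → process → extract → assign → quantify from a JSON
configuration (see `default_run_config()`), and `exec/icr2dms` exposes
the same stages on the command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","icr2dms",package="icr2dms"))')" \
  all \
  --config "$(Rscript -e 'cat(system.file("extdata","demo_config.json",package="icr2dms"))')" \
  --out /tmp/demo_run --seed 1
#> simulate: 4 channel(s), 512 x 4096 transient, seed 1
#> process: Kaiser beta=6, zerofill 1, rank none
#> extract: autocorrelation + 4 fragment scan(s)
#> assign: 459 assignment(s)
#> quantify: summary written to /tmp/demo_run/summary.json
```

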