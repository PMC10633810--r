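# Shared fixtures. Heavier simulated spectra are built lazily and memoized
# so several test files can reuse them without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## small acquisition geometry used throughout the tests: 12 T, quadrupolar
## detection, fragment range from m/z 300, 3.2 MHz sampling
small_config <- function(n_t1 = 256L, n_t2 = 4096L, mz_min_frag = 300,
                         detection_harmonic = 2L) {
  instrument_config(magnetic_field = 12, mz_max = 3000,
                    mz_min_frag = mz_min_frag, delta_t1 = 3e-6,
                    n_t1 = n_t1, n_t2 = n_t2,
                    t2_duration = n_t2 / 3.2e6,
                    detection_harmonic = detection_harmonic)
}

## noise-free single-precursor spectrum with one fragment
single_precursor_spec <- function() memo("single_prec", function() {
  cfg <- small_config()
  ch <- precursor_channel(mz = 900, charge = 1, abundance = 1,
                          fragments = data.frame(mz = 450, yield = 0.3,
                                                 charge = 1L))
  tr <- simulate_transient2d(cfg, list(ch), noise_model(), seed = 11)
  ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
})

## two precursors at m/z 900 and 1100, fragments only from the 1100 channel
two_precursor_spec <- function() memo("two_prec", function() {
  cfg <- small_config()
  chs <- list(
    precursor_channel(mz = 900, charge = 1, abundance = 1),
    precursor_channel(mz = 1100, charge = 1, abundance = 0.6,
                      fragments = data.frame(mz = c(420, 610),
                                             yield = c(0.2, 0.15),
                                             charge = 1L)))
  tr <- simulate_transient2d(cfg, chs, noise_model(), seed = 12)
  ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
})

## hand-built flat spectrum2d (constant magnitude) for arithmetic checks
flat_spectrum <- function(value = 1, n1 = 33L, n2 = 64L) {
  cfg <- small_config(n_t1 = 64L, n_t2 = 128L)
  law1 <- calibration_law(cfg$magnetic_field, 1L)
  lawH <- horizontal_law(cfg)
  fmin <- mz_to_freq(cfg$mz_max, law1)
  df1 <- 1 / (cfg$n_t1 * cfg$delta_t1)
  df2 <- 1 / cfg$t2_duration / 2  # zerofilled-once grid
  f1 <- (0:(n1 - 1L)) * df1
  f2 <- (1:n2) * df2
  structure(list(magnitude = matrix(value, n1, n2),
                 f1_axis = f1, f2_axis = f2,
                 mz_prec_axis = freq_to_mz(f1 + fmin, law1),
                 mz_frag_axis = freq_to_mz(f2, lawH),
                 vertical_law = law1, horizontal_law = lawH,
                 f_min = fmin, config = cfg,
                 provenance = list()), class = "spectrum2d")
}

## semi-analytic measured peaks of one fixture channel: theoretical m/z
## with small mass jitter, intensities = abundance * yield with relative
## noise; what a well-resolved fragment scan of that channel would yield
channel_peaks <- function(truth_table, charge, n, ppm_sd = 0.2,
                          rel_sd = 0.02, seed = 1L) {
  rows <- truth_table[truth_table$charge == charge &
                        truth_table$n_mods == n, , drop = FALSE]
  set.seed(seed)
  data.frame(
    mz = rows$mz * (1 + stats::rnorm(nrow(rows), sd = ppm_sd * 1e-6)),
    intensity = rows$abundance * rows$yield *
      pmax(1 + stats::rnorm(nrow(rows), sd = rel_sd), 0.01))
}

## assignments for a whole fixture (all charge states), per proteoform
fixture_assignments <- function(fx, lib, tol_ppm = 3, seed = 1L,
                                rel_sd = 0.02) {
  tt <- fx$truth$table
  combos <- unique(tt[, c("charge", "n_mods")])
  out <- list()
  for (r in seq_len(nrow(combos))) {
    pk <- channel_peaks(tt, combos$charge[r], combos$n_mods[r],
                        rel_sd = rel_sd,
                        seed = seed + 101L * r)
    asg <- match_fragments(pk, lib, tol_ppm = tol_ppm)
    if (!nrow(asg)) next
    asg$precursor_charge <- combos$charge[r]
    asg$proteoform_n_mods <- combos$n_mods[r]
    out[[length(out) + 1L]] <- asg
  }
  do.call(rbind, out)
}

ubi_seq <- function() protein_sequence(ubiquitin_sequence())

## distinct site occupancies used for parameter-recovery checks
## (sites M1, K6, K11, K27, K29, K33, K48, K63)
recovery_occupancy <- function() c(0.70, 0.80, 0.35, 0.40, 0.45, 0.60,
                                   0.90, 0.95)
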