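# Forward model: electron-capture products, modulation structure,
# reproducibility, and the acetylated-ubiquitin scenario builder.

test_that("electron capture yields the (n-1)+ species m/z", {
  expect_equal(capture_product_mz(874, 10), 8740 / 9, tolerance = 1e-12)
  # algebraic identity: product_mz * (n-1) = precursor_mz * n
  for (z in 2:8)
    expect_equal(capture_product_mz(1234.5, z) * (z - 1), 1234.5 * z)
  expect_error(capture_product_mz(500, 1), "neutral")
})

test_that("transients are reproducible and linear in abundance", {
  cfg <- small_config(n_t1 = 64L, n_t2 = 1024L)
  nz <- noise_model(thermal_sigma = 0.05, scintillation_cv = 0.1)
  ch <- precursor_channel(mz = 900, charge = 1,
                          fragments = data.frame(mz = 450, yield = 0.3))
  t1 <- simulate_transient2d(cfg, list(ch), nz, seed = 7)
  t2 <- simulate_transient2d(cfg, list(ch), nz, seed = 7)
  expect_identical(t1$data, t2$data)
  t3 <- simulate_transient2d(cfg, list(ch), nz, seed = 8)
  expect_false(identical(t1$data, t3$data))
  # noise-free: energy scales with abundance squared (amplitude linearly)
  ch2 <- precursor_channel(mz = 900, charge = 1, abundance = 2.5,
                           fragments = data.frame(mz = 450, yield = 0.3))
  a <- simulate_transient2d(cfg, list(ch), noise_model(), seed = 1)
  b <- simulate_transient2d(cfg, list(ch2), noise_model(), seed = 1)
  expect_equal(b$data, 2.5 * a$data, tolerance = 1e-12)
})

test_that("a single sinusoidally modulated precursor gives one diagonal peak", {
  cfg <- small_config(n_t1 = 128L, n_t2 = 2048L)
  ch <- precursor_channel(mz = 1400, charge = 1)
  tr <- simulate_transient2d(cfg, list(ch),
                             noise_model(harmonic_weights = c(0, 0)),
                             seed = 3)
  sp <- ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
  pk <- peak_pick_2d(sp, snr_threshold = 10)
  main <- pk[which.max(pk$intensity), ]
  expect_equal(main$mz_frag, 1400, tolerance = 1e-4)
  df1 <- sp$f1_axis[2] - sp$f1_axis[1]
  expect_lt(abs(main$f1 - modulation_frequency(1400, cfg)), df1)
  # all remaining peaks are far weaker than the diagonal one
  expect_true(all(pk$intensity[-which.max(pk$intensity)] <
                    0.1 * main$intensity))
})

test_that("nonsinusoidal modulation adds a vertical overtone peak", {
  cfg <- small_config(n_t1 = 256L, n_t2 = 2048L)
  ch <- precursor_channel(mz = 1400, charge = 1)
  tr <- simulate_transient2d(cfg, list(ch),
                             noise_model(harmonic_weights = c(0.3)),
                             seed = 3)
  sp <- ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
  fmod <- modulation_frequency(1400, cfg)
  df1 <- sp$f1_axis[2] - sp$f1_axis[1]
  col <- which.min(abs(sp$f2_axis - mz_to_freq(1400, sp$horizontal_law)))
  row1 <- which.min(abs(sp$f1_axis - fmod))
  row2 <- which.min(abs(sp$f1_axis - 2 * fmod))
  expect_lt(abs(sp$f1_axis[row2] - 2 * fmod), df1)
  h1 <- sp$magnitude[row1, col]
  h2 <- sp$magnitude[row2, col]
  expect_gt(h2, 0.15 * h1)  # overtone clearly present
  expect_lt(h2, h1)         # but weaker than the fundamental
})

test_that("scintillation produces a vertical streak at the species column", {
  cfg <- small_config(n_t1 = 128L, n_t2 = 2048L)
  ch <- precursor_channel(mz = 1200, charge = 1)
  tr <- simulate_transient2d(cfg, list(ch),
                             noise_model(scintillation_cv = 0.3), seed = 5)
  sp <- ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
  col <- which.min(abs(sp$f2_axis - mz_to_freq(1200, sp$horizontal_law)))
  ## off-peak vertical bins of the species column carry excess energy
  fmod <- modulation_frequency(1200, cfg)
  row1 <- which.min(abs(sp$f1_axis - fmod))
  rows <- setdiff(seq_len(nrow(sp$magnitude)), (row1 - 3):(row1 + 3))
  streak <- stats::median(sp$magnitude[rows, col])
  blank <- stats::median(sp$magnitude[rows, col + 200])
  expect_gt(streak, 5 * blank)
})

test_that("1-omega leakage duplicates lines at half the detected frequency", {
  cfg <- small_config(n_t1 = 128L, n_t2 = 2048L)
  ch <- precursor_channel(mz = 900, charge = 1)
  tr <- simulate_transient2d(cfg, list(ch),
                             noise_model(leakage_1w = 0.2,
                                         harmonic_weights = c(0, 0)),
                             seed = 5)
  sp <- ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
  f2 <- mz_to_freq(900, sp$horizontal_law)
  row1 <- which.min(abs(sp$f1_axis - modulation_frequency(900, cfg)))
  main <- sp$magnitude[row1, which.min(abs(sp$f2_axis - f2))]
  sub <- sp$magnitude[row1, which.min(abs(sp$f2_axis - f2 / 2))]
  expect_gt(sub, 0.1 * main)
  expect_lt(sub, 0.3 * main)
  ## the duplicate appears at twice the apparent m/z: a 1/2-slope point
  mz_app <- freq_to_mz(f2 / 2, sp$horizontal_law)
  expect_equal(mz_app, 1800, tolerance = 1e-6)
})

test_that("out-of-range species and inconsistent yields are rejected", {
  cfg <- small_config(n_t1 = 64L, n_t2 = 1024L)
  expect_error(simulate_transient2d(
    cfg, list(precursor_channel(mz = 500, charge = 1)), seed = 1),
    "precursor_mz_range")
  expect_error(simulate_transient2d(
    cfg, list(precursor_channel(mz = 900, charge = 1,
                                fragments = data.frame(mz = 100, yield = 0.1))),
    seed = 1), "mz_min_frag")
  expect_error(precursor_channel(
    mz = 900, charge = 1,
    fragments = data.frame(mz = 450, yield = 0.9), capture_yield = 0.3),
    "summing")
})

test_that("fixture yields encode a deterministic single-site ground truth", {
  occ <- c(0, 1, 0, 0, 0, 0, 0, 0)  # K6 fully occupied, nothing else
  fx <- ubiquitin_fixture(occ, charge_states = 8L, n_mods = 1L,
                          capture_yield = 0)
  tt <- fx$truth$table
  cfr <- tt[tt$series == "c", ]
  # every c fragment covering K6 carries exactly one acetyl, earlier ones none
  expect_true(all(cfr$n_frag_mods[cfr$index >= 6] == 1L))
  expect_true(all(cfr$n_frag_mods[cfr$index < 6] == 0L))
  expect_equal(fx$truth$conditional_site_prob[["1"]][["6"]], 1)
  # bit-identical on rebuild
  fx2 <- ubiquitin_fixture(occ, charge_states = 8L, n_mods = 1L,
                           capture_yield = 0)
  expect_identical(fx$truth$table, fx2$truth$table)
})

test_that("uniform occupancies split yields hypergeometrically over spans", {
  fx <- ubiquitin_fixture(rep(0.5, 8), charge_states = 8L, n_mods = 4L)
  tt <- fx$truth$table
  ## c27 spans candidate sites {1, 6, 11, 27}: k = 4 of the 8 sites, so
  ## P(j | total 4) = C(4,j) C(4,4-j) / C(8,4) -- exhaustive-enumeration value
  sub <- tt[tt$series == "c" & tt$index == 27, ]
  got <- sub$yield / sum(sub$yield)
  expected <- choose(4, 0:4) * choose(4, 4 - 0:4) / choose(8, 4)
  expect_equal(got[order(sub$n_frag_mods)], expected, tolerance = 1e-9)
  expect_error(ubiquitin_fixture(c(1, 0, 0, 0, 0, 0, 0, 0),
                                 charge_states = 8L, n_mods = 4L),
               "inconsistent")
})
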