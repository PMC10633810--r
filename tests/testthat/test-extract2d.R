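# Structured extraction: autocorrelation line, fragment/precursor scans,
# capture lines, SNR measurement and artifact labeling.

test_that("autocorrelation line shows every modulated precursor", {
  sp <- two_precursor_spec()
  ac <- autocorrelation_line(sp)
  expect_s3_class(ac, "scan1d")
  df1 <- sp$f1_axis[2] - sp$f1_axis[1]
  for (mz0 in c(900, 1100)) {
    win <- abs(ac$axis - mz0) < 25
    mzpk <- ac$axis[win][which.max(ac$intensity[win])]
    ## within one vertical bin of the injected species
    dmz_bin <- df1 * mz0^2 / sp$vertical_law$coeff_a
    expect_lt(abs(mzpk - mz0), dmz_bin)
  }
  ## the 900 species is more abundant: ordering preserved on the diagonal
  expect_gt(snr_1d(ac, 900), snr_1d(ac, 1100))
  ## empty spectrum -> all-zero scan
  blank <- flat_spectrum(0)
  expect_true(all(autocorrelation_line(blank)$intensity == 0))
})

test_that("fragment scans sum adjacent rows linearly", {
  sp <- single_precursor_spec()
  s1 <- fragment_scan(sp, 900, 1)
  i <- which.min(abs(sp$mz_prec_axis - 900))
  expect_equal(sum(s1$intensity), sum(sp$magnitude[i, ]))
  ## constant spectrum: summing 5 rows gives 5x each value
  flat <- flat_spectrum(2)
  s5 <- fragment_scan(flat, 1500, 5)
  expect_true(all(s5$intensity == 10))
  expect_identical(s5$meta$rows_summed, 5L)
  ## exact linearity: 5-row scan equals the sum of the 5 single rows
  rows <- (i - 2):(i + 2)
  manual <- colSums(sp$magnitude[rows, ])
  s5b <- fragment_scan(sp, 900, 5)
  expect_equal(sort(s5b$intensity), sort(manual))
  expect_error(fragment_scan(sp, 900, 4), "odd")
  expect_error(fragment_scan(sp, 5000, 1), "out-of-range")
})

test_that("precursor scans recover which precursor made a fragment", {
  sp <- two_precursor_spec()
  ## fragments at 420/610 come only from the m/z 1100 channel
  for (mzf in c(420, 610)) {
    ps <- precursor_scan(sp, mzf)
    expect_identical(ps$meta$kind, "precursor_scan")
    pk <- ps$axis[which.max(ps$intensity)]
    expect_lt(abs(pk - 1100), 12)
  }
  ## a blank column is all zeros in a blank spectrum
  expect_true(all(precursor_scan(flat_spectrum(0), 1000)$intensity == 0))
  expect_error(precursor_scan(sp, 100), "horizontal range")
})

test_that("capture lines have slope (n-1)/n and show the reduced product", {
  sp0 <- flat_spectrum(1)
  expect_equal(capture_line(sp0, 10)$meta$slope, 0.9)
  expect_equal(capture_line(sp0, 2)$meta$slope, 0.5)
  expect_error(capture_line(sp0, 1), "charge")
  ## fixture: 10+ precursor with a capture product on the 9/10 line
  cfg <- small_config(n_t1 = 256L, n_t2 = 4096L)
  ch <- precursor_channel(mz = 874, charge = 10, abundance = 1,
                          capture_yield = 0.4)
  tr <- simulate_transient2d(cfg, list(ch), noise_model(), seed = 21)
  sp <- ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
  cl <- capture_line(sp, 10)
  mzpk <- cl$axis[which.max(cl$intensity)]
  expect_equal(mzpk, capture_product_mz(874, 10), tolerance = 2e-3)
})

test_that("scan SNR is ratio-invariant and calibrated on known noise", {
  set.seed(31)
  n <- 2000
  noise <- stats::rnorm(n)
  axis <- seq(300, 1500, length.out = n)
  y <- noise
  y[1000] <- 100
  scan <- structure(list(axis = axis, intensity = y,
                         meta = list(kind = "fragment_scan", anchor = NA,
                                     rows_summed = 1L)), class = "scan1d")
  s <- snr_1d(scan, axis[1000])
  expect_gt(s, 70); expect_lt(s, 130)   # ~100 within 30%
  ## pure noise: low SNR anywhere
  scan0 <- structure(list(axis = axis, intensity = noise,
                          meta = list(kind = "fragment_scan", anchor = NA,
                                      rows_summed = 1L)), class = "scan1d")
  expect_lt(snr_1d(scan0, axis[500]), 6)
  ## scaling leaves the ratio unchanged
  scan10 <- scan; scan10$intensity <- 10 * scan10$intensity
  expect_equal(snr_1d(scan10, axis[1000]), s)
})

test_that("1D peak picking refines centroids and applies the threshold", {
  sp <- single_precursor_spec()
  fs <- fragment_scan(sp, 900, 1)
  pk <- pick_peaks_1d(fs, snr_threshold = 10)
  expect_gte(nrow(pk), 2L)
  expect_lt(min(abs(pk$mz - 450)), 0.05)
  expect_lt(min(abs(pk$mz - 900)), 0.05)
  expect_identical(nrow(pick_peaks_1d(fs, snr_threshold = 1e9)), 0L)
})

test_that("autocorrelation SNR beats a 1D spectrum at the method's scan budget", {
  ## 2D experiment with 256 encoding scans vs a 1D spectrum averaging 4
  ## scans -- the same 64:1 scan-count proportion the 2D method uses
  ## against its 1D reference acquisition
  cfg <- small_config(n_t1 = 256L, n_t2 = 2048L)
  sig <- 0.5
  tr <- simulate_transient2d(cfg, list(precursor_channel(mz = 900, charge = 1)),
                             noise_model(thermal_sigma = sig), seed = 5)
  sp <- ft2d_magnitude(zerofill(apodize_kaiser(tr, 6), 1))
  s2d <- snr_1d(autocorrelation_line(sp), 900)
  ## matched per-scan conditions for the 1D reference, 4 scans averaged
  t2 <- (0:(cfg$n_t2 - 1L)) / 3.2e6
  law2 <- horizontal_law(cfg)
  set.seed(6)
  x <- cos(2 * pi * mz_to_freq(900, law2) * t2) * exp(-t2 / cfg$t2_duration) +
    stats::rnorm(cfg$n_t2, sd = sig / sqrt(4))
  xw <- x * kaiser_window(cfg$n_t2, 6)
  X <- Mod(stats::fft(c(xw, numeric(cfg$n_t2))))[2:(cfg$n_t2 + 1L)]
  f2ax <- (1:cfg$n_t2) / (2 * cfg$n_t2 / 3.2e6)
  scan <- structure(list(axis = rev(freq_to_mz(f2ax, law2)),
                         intensity = rev(X),
                         meta = list(kind = "fragment_scan", anchor = NA,
                                     rows_summed = 1L)), class = "scan1d")
  expect_gt(s2d / snr_1d(scan, 900), 2)
})

test_that("artifact labeling identifies the known line equations", {
  sp <- two_precursor_spec()
  mk <- function(mzp, mzf) data.frame(
    mz_prec = mzp, mz_frag = mzf,
    f1 = mz_to_freq(mzp, sp$vertical_law) - sp$f_min,
    f2 = mz_to_freq(mzf, sp$horizontal_law),
    row = 1L, col = 5L, intensity = 1, snr = 10)
  pks <- rbind(mk(900, 900.0005), mk(450.1, 900.2), mk(874, 971.11),
               mk(1000, 612))
  lab <- flag_artifacts(pks, sp, charges = 2:10)$label
  expect_identical(lab[1], "autocorrelation")
  expect_identical(lab[2], "subharmonic_half_slope")
  expect_identical(lab[3], "capture_line(10)")
  expect_identical(lab[4], "analyte")
})
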