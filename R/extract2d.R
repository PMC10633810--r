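# Structured extraction from a 2D magnitude spectrum: autocorrelation line,
# electron-capture lines, fragment and precursor ion scans, SNR measurement
# and artifact labeling.

.scan1d <- function(axis, intensity, kind, anchor = NA_real_,
                    rows_summed = 1L, extra = list()) {
  o <- order(axis)
  structure(list(axis = axis[o], intensity = intensity[o],
                 meta = c(list(kind = kind, anchor = anchor,
                               rows_summed = rows_summed), extra)),
            class = "scan1d")
}

#' @export
print.scan1d <- function(x, ...) {
  cat(sprintf("<scan1d:%s> %d points, m/z %.2f-%.2f%s\n",
              x$meta$kind, length(x$axis), min(x$axis), max(x$axis),
              if (is.finite(x$meta$anchor))
                sprintf(", anchor %.3f", x$meta$anchor) else ""))
  invisible(x)
}

## linear interpolation of one spectrum row/column on its frequency grid
.interp_grid <- function(values, df, f) {
  pos <- f / df                       # grid position, 1-based values[k] at k*df
  j0 <- floor(pos)
  w <- pos - j0
  n <- length(values)
  ok <- j0 >= 1 & j0 <= n - 1
  out <- numeric(length(f))
  out[ok] <- values[j0[ok]] * (1 - w[ok]) + values[j0[ok] + 1L] * w[ok]
  exact <- j0 == n & w < 1e-9
  out[exact] <- values[n]
  attr(out, "flagged") <- !(ok | exact)
  out
}

#' Extract the autocorrelation line of a 2D spectrum
#'
#' For each vertical (precursor) bin, the intensity at the horizontal bin
#' whose m/z equals that precursor m/z, with linear interpolation between
#' the two nearest horizontal bins. Samples whose precursor m/z falls
#' outside the horizontal range are set to 0 and flagged.
#'
#' @param spec A `spectrum2d`.
#' @return A `scan1d` with the precursor m/z axis (kind
#'   `"autocorrelation"`); `meta$n_flagged` counts out-of-range samples.
#' @export
autocorrelation_line <- function(spec) {
  stopifnot(inherits(spec, "spectrum2d"))
  df2 <- spec$f2_axis[2] - spec$f2_axis[1]
  mzs <- spec$mz_prec_axis
  f2t <- mz_to_freq(mzs, spec$horizontal_law)
  inten <- numeric(length(mzs))
  nflag <- 0L
  for (i in seq_along(mzs)) {
    v <- .interp_grid(spec$magnitude[i, ], df2, f2t[i])
    if (attr(v, "flagged")[1]) nflag <- nflag + 1L
    inten[i] <- v[1]
  }
  .scan1d(mzs, inten, "autocorrelation", extra = list(n_flagged = nflag))
}

## nearest vertical row of a precursor m/z
.row_of_mz_prec <- function(spec, mz_prec) {
  f1 <- mz_to_freq(mz_prec, spec$vertical_law) - spec$f_min
  df1 <- spec$f1_axis[2] - spec$f1_axis[1]
  i <- round(f1 / df1) + 1L
  if (i < 1L || i > nrow(spec$magnitude))
    stop("precursor m/z ", signif(mz_prec, 8),
         " outside the vertical range (out-of-range)")
  as.integer(i)
}

#' Fragment ion scan (horizontal cross-section, adjacent rows summed)
#'
#' Sums the `n_adjacent` horizontal rows centered on the vertical bin
#' nearest `mz_prec`. Summing adjacent scans recovers complete fragment
#' isotope envelopes when the precursor isotopic envelope spans several
#' vertical bins.
#'
#' @param spec A `spectrum2d`.
#' @param mz_prec Precursor m/z anchoring the scan.
#' @param n_adjacent Odd number of rows to sum (default 5).
#' @return A `scan1d` over the fragment m/z axis (kind `"fragment_scan"`).
#' @export
fragment_scan <- function(spec, mz_prec, n_adjacent = 5L) {
  stopifnot(inherits(spec, "spectrum2d"))
  n_adjacent <- as.integer(n_adjacent)
  if (n_adjacent < 1L || n_adjacent %% 2L == 0L)
    stop("n_adjacent must be an odd positive integer")
  i <- .row_of_mz_prec(spec, mz_prec)
  h <- n_adjacent %/% 2L
  rows <- (i - h):(i + h)
  rows <- rows[rows >= 1L & rows <= nrow(spec$magnitude)]
  inten <- colSums(spec$magnitude[rows, , drop = FALSE])
  .scan1d(spec$mz_frag_axis, inten, "fragment_scan", anchor = mz_prec,
          rows_summed = n_adjacent)
}

#' Precursor ion scan (vertical cross-section)
#'
#' @param spec A `spectrum2d`.
#' @param mz_frag Fragment m/z; the vertical column at the nearest
#'   horizontal bin is returned over the precursor m/z axis.
#' @return A `scan1d` (kind `"precursor_scan"`).
#' @export
precursor_scan <- function(spec, mz_frag) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (mz_frag < min(spec$mz_frag_axis) || mz_frag > max(spec$mz_frag_axis))
    stop("fragment m/z outside the horizontal range")
  f2 <- mz_to_freq(mz_frag, spec$horizontal_law)
  df2 <- spec$f2_axis[2] - spec$f2_axis[1]
  j <- max(1L, min(ncol(spec$magnitude), as.integer(round(f2 / df2))))
  .scan1d(spec$mz_prec_axis, spec$magnitude[, j], "precursor_scan",
          anchor = mz_frag)
}

#' Electron-capture line of a given precursor charge state
#'
#' Samples the 2D spectrum along `mz_prec = ((charge-1)/charge) * mz_frag`,
#' the locus of singly charge-reduced products of `charge`+ precursors.
#'
#' @param spec A `spectrum2d`.
#' @param charge Precursor charge state (at least 2).
#' @return A `scan1d` over the fragment m/z axis (kind `"capture_line"`);
#'   `meta$slope` holds `(charge-1)/charge`.
#' @export
capture_line <- function(spec, charge) {
  stopifnot(inherits(spec, "spectrum2d"))
  charge <- as.integer(charge)
  if (charge < 2L) stop("charge must be >= 2")
  slope <- (charge - 1L) / charge
  df1 <- spec$f1_axis[2] - spec$f1_axis[1]
  mzf <- spec$mz_frag_axis
  mzp <- slope * mzf
  f1 <- mz_to_freq(pmax(mzp, 1e-12), spec$vertical_law) - spec$f_min
  inten <- numeric(length(mzf))
  ok <- mzp <= spec$config$mz_max & f1 > 0
  for (j in which(ok)) {
    v <- .interp_grid(spec$magnitude[, j], df1, f1[j])
    inten[j] <- v[1]
  }
  .scan1d(mzf, inten, "capture_line", extra = list(slope = slope,
                                                   charge = charge))
}

#' Signal-to-noise ratio of a peak in a 1D scan
#'
#' Peak height is the maximum within +/- 3 bins of the position nearest
#' `mz`; the noise is `1.4826 * MAD` of the scan with +/- `mask_halfwidth`
#' bins around the peak masked.
#'
#' @param scan A `scan1d`.
#' @param mz Position of the peak on the scan axis.
#' @param mask_halfwidth Bins masked around the peak for the noise estimate.
#' @return SNR (ratio, dimensionless).
#' @export
snr_1d <- function(scan, mz, mask_halfwidth = 10L) {
  stopifnot(inherits(scan, "scan1d"))
  if (mz < min(scan$axis) || mz > max(scan$axis))
    stop("mz outside the scan axis")
  i <- which.min(abs(scan$axis - mz))
  n <- length(scan$intensity)
  win <- max(1L, i - 3L):min(n, i + 3L)
  ipk <- win[which.max(scan$intensity[win])]
  height <- scan$intensity[ipk]
  mask <- max(1L, ipk - mask_halfwidth):min(n, ipk + mask_halfwidth)
  rest <- scan$intensity[-mask]
  noise <- stats::mad(rest)
  if (noise <= 0) noise <- .Machine$double.eps
  height / noise
}

#' Pick peaks in a 1D scan
#'
#' Local maxima with parabolic centroid refinement (in index space, mapped
#' back through the scan axis) and SNR against a robust noise estimate of
#' the peak-masked scan.
#'
#' @param scan A `scan1d`.
#' @param snr_threshold Minimum SNR.
#' @param mask_halfwidth Bins masked around candidate peaks for the noise
#'   re-estimate.
#' @return `data.frame` with columns `mz`, `intensity`, `snr`.
#' @export
pick_peaks_1d <- function(scan, snr_threshold = 3, mask_halfwidth = 3L) {
  stopifnot(inherits(scan, "scan1d"))
  y <- scan$intensity
  n <- length(y)
  if (n < 3L) return(data.frame(mz = numeric(0), intensity = numeric(0),
                                snr = numeric(0)))
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                  y[2:(n - 1L)] >= y[3:n] & y[2:(n - 1L)] > 0) + 1L
  if (!length(cand)) return(data.frame(mz = numeric(0),
                                       intensity = numeric(0),
                                       snr = numeric(0)))
  noise <- stats::mad(y)
  snr <- y[cand] / pmax(noise, .Machine$double.eps)
  sel <- cand[snr >= snr_threshold]
  maskc <- unique(unlist(lapply(sel, function(jc)
    max(1L, jc - mask_halfwidth):min(n, jc + mask_halfwidth))))
  if (length(maskc) && length(maskc) < n - 8L) noise <- stats::mad(y[-maskc])
  snr <- y[cand] / pmax(noise, .Machine$double.eps)
  keep <- snr >= snr_threshold
  cand <- cand[keep]; snr <- snr[keep]
  if (!length(cand)) return(data.frame(mz = numeric(0),
                                       intensity = numeric(0),
                                       snr = numeric(0)))
  mz <- numeric(length(cand))
  for (t in seq_along(cand)) {
    j <- cand[t]
    den <- y[j - 1L] - 2 * y[j] + y[j + 1L]
    d <- if (is.finite(den) && den < 0) 0.5 * (y[j - 1L] - y[j + 1L]) / den else 0
    d <- max(min(d, 0.5), -0.5)
    mz[t] <- if (d >= 0)
      scan$axis[j] + d * (scan$axis[min(j + 1L, n)] - scan$axis[j])
    else
      scan$axis[j] + d * (scan$axis[j] - scan$axis[max(j - 1L, 1L)])
  }
  out <- data.frame(mz = mz, intensity = y[cand], snr = snr)
  out[order(-out$intensity), , drop = FALSE]
}

#' Label 2D peaks as analyte signal or known artifact classes
#'
#' Each picked peak is tested for membership of the known line equations:
#' autocorrelation (`mz_prec = mz_frag`), electron-capture lines
#' (`mz_prec = ((n-1)/n) mz_frag` for the supplied charges), vertical
#' harmonics of the modulation (vertical frequency at `k` times the
#' modulation frequency of the diagonal species), the 1-omega subharmonic
#' at slope 1/2, and scintillation streaks (columns whose off-peak median
#' magnitude is in excess -- note that the vertical sinc skirts of very
#' intense lines under a rectangular t1 window are flagged too).
#' Membership tolerance is `tol_ppm` in the fragment dimension and one
#' vertical bin in the precursor dimension.
#'
#' @param peaks `data.frame` from [peak_pick_2d()].
#' @param spec The `spectrum2d` the peaks came from.
#' @param charges Charge states tested for capture lines (default 2:10).
#' @param harmonics Vertical harmonic orders tested (default 2:3).
#' @param tol_ppm Fragment-dimension tolerance in ppm (default 20).
#' @param streak_factor Excess factor (median + factor * MAD of the
#'   off-peak column medians) above which a column is called a
#'   scintillation streak.
#' @return The peak table with an added `label` column.
#' @export
flag_artifacts <- function(peaks, spec, charges = 2:10, harmonics = 2:3,
                           tol_ppm = 20, streak_factor = 8) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (!nrow(peaks)) {
    peaks$label <- character(0)
    return(peaks)
  }
  df1 <- spec$f1_axis[2] - spec$f1_axis[1]
  label <- rep("analyte", nrow(peaks))
  ## vertical frequency predicted for a precursor at m/z mzp
  f1_of_mz <- function(mzp)
    mz_to_freq(mzp, spec$vertical_law) - spec$f_min
  within_line <- function(mzp_pred) {
    ok <- mzp_pred <= spec$config$mz_max & mzp_pred > 0
    d <- rep(Inf, length(mzp_pred))
    d[ok] <- abs(peaks$f1[ok] - f1_of_mz(mzp_pred[ok]))
    ## one vertical bin, plus the vertical image of a tol_ppm fragment error
    slack <- df1 + spec$vertical_law$coeff_a / mzp_pred^2 *
      (tol_ppm * 1e-6 * mzp_pred)
    d <= slack
  }
  ## harmonic(k): vertical frequency = k x modulation frequency of the
  ## species sitting at the fragment m/z
  for (k in rev(harmonics)) {
    fmodk <- k * pmax(f1_of_mz(pmin(peaks$mz_frag, spec$config$mz_max)), 0)
    hit <- abs(peaks$f1 - fmodk) <= df1 & peaks$mz_frag <= spec$config$mz_max
    label[hit] <- paste0("harmonic(", k, ")")
  }
  for (n in rev(sort(charges))) {
    hit <- within_line((n - 1) / n * peaks$mz_frag)
    label[hit] <- paste0("capture_line(", n, ")")
  }
  hit <- within_line(0.5 * peaks$mz_frag)
  label[hit] <- "subharmonic_half_slope"
  ## autocorrelation last: diagonal membership wins over the other lines
  hit <- within_line(peaks$mz_frag)
  label[hit] <- "autocorrelation"
  ## scintillation streaks: columns whose OFF-peak rows carry excess
  ## energy (the peaks themselves are masked so ordinary signal columns
  ## are not mistaken for streaks)
  m <- spec$magnitude
  msk <- m
  n1 <- nrow(m)
  for (t in seq_len(nrow(peaks))) {
    rows <- max(1L, peaks$row[t] - 2L):min(n1, peaks$row[t] + 2L)
    msk[rows, peaks$col[t]] <- 0
  }
  ## a streak elevates the whole column (broadband), so use the column's
  ## median off-peak magnitude; harmonics concentrated in a few rows do
  ## not move the median
  colE <- apply(msk, 2, stats::median)
  thr <- stats::median(colE) + streak_factor * stats::mad(colE)
  streak_cols <- which(colE > thr)
  is_streak <- label == "analyte" & peaks$col %in% streak_cols
  label[is_streak] <- "scintillation_streak"
  peaks$label <- label
  peaks
}
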