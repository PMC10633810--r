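# Magnitude-mode processing chain: Kaiser apodization, zero filling, 2D
# Fourier transform with calibrated axes, low-rank Hankel denoising of the
# t1 interferograms, and 2D peak picking.

#' Kaiser window
#' @param n Window length.
#' @param beta Shape parameter (0 gives the rectangular window).
#' @return Numeric vector of length `n`, symmetric with maximum at center.
#' @export
kaiser_window <- function(n, beta) {
  if (beta < 0) stop("beta must be nonnegative")
  if (beta == 0) return(rep(1, n))
  x <- 2 * (0:(n - 1)) / (n - 1) - 1
  besselI(beta * sqrt(pmax(1 - x^2, 0)), 0) / besselI(beta, 0)
}

#' Apodize a 2D transient with a Kaiser window
#'
#' @param transient A `transient2d`.
#' @param beta Kaiser shape parameter (default 6; 0 leaves the data
#'   unchanged).
#' @param dims `"t2"` (default) applies the window along each transient
#'   row; `"both"` additionally windows the t1 columns.
#' @return The apodized `transient2d`.
#' @export
apodize_kaiser <- function(transient, beta = 6, dims = c("t2", "both")) {
  stopifnot(inherits(transient, "transient2d"))
  dims <- match.arg(dims)
  if (beta < 0) stop("beta must be nonnegative")
  w2 <- kaiser_window(ncol(transient$data), beta)
  transient$data <- sweep(transient$data, 2, w2, `*`)
  if (dims == "both") {
    w1 <- kaiser_window(nrow(transient$data), beta)
    transient$data <- transient$data * w1
  }
  transient$apodization <- list(beta = beta, dims = dims)
  transient
}

#' Zero-fill a 2D transient along t2
#'
#' @param transient A `transient2d`.
#' @param factor Nonnegative integer; the t2 length is multiplied by
#'   `2^factor` with trailing zeros (0 is the identity).
#' @return The zero-filled `transient2d` (the stored `n_t2` is updated;
#'   the sampling interval is unchanged).
#' @export
zerofill <- function(transient, factor = 1L) {
  stopifnot(inherits(transient, "transient2d"))
  factor <- as.integer(factor)
  if (factor < 0) stop("factor must be a nonnegative integer")
  if (factor == 0L) return(transient)
  n2 <- ncol(transient$data)
  pad <- matrix(0, nrow(transient$data), n2 * (2^factor - 1L))
  transient$data <- cbind(transient$data, pad)
  transient$zerofill <- factor
  transient
}

#' 2D Fourier transform to a calibrated magnitude spectrum
#'
#' Transforms along t2 (rows) to the complex fragment-dimension spectrum,
#' optionally denoises the resulting t1 interferograms ([sane_denoise()]),
#' removes the per-column t1 mean (the unmodulated background), transforms
#' along t1 and takes the magnitude. The horizontal axis is calibrated at
#' the configured detection harmonic; the vertical axis maps modulation
#' frequency back to precursor m/z through the fundamental law and the
#' digital modulation floor.
#'
#' @param transient A `transient2d` (possibly apodized / zero-filled).
#' @param rank Optional SANE rank; `NULL` skips denoising.
#' @param rank_seed Seed for the randomized projector used by the denoiser.
#' @param demean_t1 Remove each interferogram's mean before the t1
#'   transform (default TRUE).
#' @return Object of class `spectrum2d`: nonnegative magnitude matrix
#'   (rows = vertical/precursor bins, columns = horizontal/fragment bins),
#'   frequency and m/z axes, calibration laws and a provenance record.
#' @export
ft2d_magnitude <- function(transient, rank = NULL, rank_seed = 1L,
                           demean_t1 = TRUE) {
  stopifnot(inherits(transient, "transient2d"))
  config <- transient$config
  n1 <- nrow(transient$data)
  n2 <- ncol(transient$data)
  dt2 <- config$t2_duration / config$n_t2
  ## t2 transform per row; keep positive-frequency bins 1..n2/2
  F2 <- stats::mvfft(t(transient$data))          # n2 x n1, FFT of each row
  keep2 <- 2:(n2 %/% 2 + 1L)                     # drop DC, keep k = 1..n2/2
  interf <- t(F2[keep2, , drop = FALSE])         # n1 x n2/2 complex
  if (!is.null(rank))
    interf <- sane_denoise(interf, rank = rank, seed = rank_seed)
  if (demean_t1)
    interf <- sweep(interf, 2, colMeans(interf), `-`)
  F1 <- stats::mvfft(interf)                     # t1 transform per column
  keep1 <- 1:(n1 %/% 2 + 1L)                     # k = 0..n1/2
  mag <- Mod(F1[keep1, , drop = FALSE])
  df2 <- 1 / (n2 * dt2)
  df1 <- 1 / (n1 * config$delta_t1)
  f2_axis <- (keep2 - 1L) * df2
  f1_axis <- (keep1 - 1L) * df1
  law1 <- .fundamental_law(config)
  lawH <- horizontal_law(config)
  fmin <- .f_min(config)
  structure(list(
    magnitude = mag,
    f1_axis = f1_axis, f2_axis = f2_axis,
    mz_prec_axis = freq_to_mz(f1_axis + fmin, law1),
    mz_frag_axis = freq_to_mz(f2_axis, lawH),
    vertical_law = law1, horizontal_law = lawH, f_min = fmin,
    config = config,
    provenance = list(rank = rank, rank_seed = rank_seed,
                      demean_t1 = demean_t1,
                      apodization = transient$apodization,
                      zerofill = transient$zerofill,
                      seed = transient$seed)),
    class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf(
    "<spectrum2d> %d x %d; precursor m/z %.1f-%.1f, fragment m/z %.1f-%.1f\n",
    nrow(x$magnitude), ncol(x$magnitude),
    min(x$mz_prec_axis), max(x$mz_prec_axis),
    min(x$mz_frag_axis), max(x$mz_frag_axis)))
  invisible(x)
}

#' Low-rank Hankel (SANE-style) denoising
#'
#' Each column of `x` (a t1 interferogram) is embedded in a Hankel matrix
#' of window length `window`, projected onto a low-dimensional random
#' subspace with one re-orthogonalized power iteration, truncated to the
#' given rank, and reconstructed by anti-diagonal averaging. Noise outside
#' the signal subspace -- including the vertical scintillation streaks of a
#' 2D spectrum -- is suppressed while modulated components are preserved.
#'
#' @param x Real or complex matrix; columns are treated as independent
#'   signals.
#' @param rank Truncation rank (at least 1 and smaller than the Hankel
#'   embedding permits).
#' @param window Hankel window length; default `min(floor(n/2), 512)`.
#' @param seed Seed for the randomized projector (the result is
#'   deterministic given the seed).
#' @param oversample Extra random directions beyond `rank` (default 8).
#' @param n_iter Re-orthogonalized power iterations (default 1).
#' @return Matrix of the same shape and mode as `x`.
#' @export
sane_denoise <- function(x, rank, window = NULL, seed = 1L,
                         oversample = 8L, n_iter = 1L) {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be >= 1")
  if (is.null(window)) window <- min(n %/% 2L, 512L)
  L <- as.integer(window); M <- n - L + 1L
  if (rank >= min(L, M))
    stop("rank (", rank, ") exceeds the Hankel embedding size (min(",
         L, ", ", M, "))")
  idx <- outer(seq_len(L), seq_len(M) - 1L, `+`)   # Hankel index map
  cplx <- is.complex(x)
  set.seed(as.integer(seed))
  p <- rank + as.integer(oversample)
  out <- x
  counts <- pmin(seq_len(n), L, M, n - seq_len(n) + 1L)
  for (col in seq_len(ncol(x))) {
    s <- x[, col]
    H <- matrix(s[idx], L, M)
    omega <- matrix(stats::rnorm(M * p), M, p)
    if (cplx) omega <- omega + 1i * matrix(stats::rnorm(M * p), M, p)
    Y <- H %*% omega
    Q <- qr.Q(qr(Y))
    for (it in seq_len(n_iter)) {
      Z <- Conj(t(H)) %*% Q
      Q <- qr.Q(qr(H %*% Z))
    }
    B <- Conj(t(Q)) %*% H
    sv <- svd(B, nu = rank, nv = rank)
    r <- seq_len(rank)
    Hr <- (Q %*% sv$u[, r, drop = FALSE]) %*%
      (sv$d[r] * Conj(t(sv$v[, r, drop = FALSE])))
    acc <- if (cplx) complex(n) else numeric(n)
    for (j in seq_len(M))
      acc[j:(j + L - 1L)] <- acc[j:(j + L - 1L)] + Hr[, j]
    out[, col] <- acc / counts
  }
  if (vec_in) out[, 1L] else out
}

#' Pick peaks in a 2D magnitude spectrum
#'
#' Local maxima over a 3x3 neighborhood with signal-to-noise at least
#' `snr_threshold`; the noise is a per-row robust estimate (1.4826 x
#' median absolute deviation computed after masking picked peaks, two
#' passes). Peak centroids are refined by one-dimensional parabolic
#' interpolation in each dimension.
#'
#' @param spec A `spectrum2d`.
#' @param snr_threshold Minimum SNR (> 0).
#' @param mask_halfwidth Bins masked on each side of a peak when
#'   re-estimating the row noise (default 3).
#' @return `data.frame` with columns `mz_prec`, `mz_frag`, `f1`, `f2`,
#'   `row`, `col`, `intensity`, `snr`, sorted by decreasing intensity.
#' @export
peak_pick_2d <- function(spec, snr_threshold = 3, mask_halfwidth = 3L) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (snr_threshold <= 0) stop("snr_threshold must be positive")
  m <- spec$magnitude
  n1 <- nrow(m); n2 <- ncol(m)
  if (n1 < 3L || n2 < 3L) return(.empty_peaks())
  pad <- matrix(-Inf, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- m
  ctr <- pad[2:(n1 + 1L), 2:(n2 + 1L)]
  ismax <- ctr > 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(n1 + 1L + di), (2 + dj):(n2 + 1L + dj)]
    ismax <- ismax & (ctr > nb | (ctr == nb & (di > 0 | (di == 0 & dj > 0))))
  }
  cand <- which(ismax, arr.ind = TRUE)
  if (!nrow(cand)) return(.empty_peaks())
  row_noise_raw <- apply(m, 1, function(r) stats::mad(r))
  for (pass in 1:2) {
    noise <- row_noise_raw[cand[, 1]]
    snr <- m[cand] / pmax(noise, .Machine$double.eps)
    keep <- snr >= snr_threshold
    if (pass == 1L) {
      sel <- cand[keep, , drop = FALSE]
      ## re-estimate row noise with picked peaks masked
      for (i in unique(sel[, 1])) {
        cols <- sel[sel[, 1] == i, 2]
        maskc <- unique(unlist(lapply(cols, function(jc)
          max(1L, jc - mask_halfwidth):min(n2, jc + mask_halfwidth))))
        rest <- m[i, -maskc]
        if (length(rest) > 8L) row_noise_raw[i] <- stats::mad(rest)
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  snr <- snr[keep]
  if (!nrow(cand)) return(.empty_peaks())
  refine <- function(y0, y1, y2) {
    den <- y0 - 2 * y1 + y2
    if (!is.finite(den) || den >= 0) return(0)
    d <- 0.5 * (y0 - y2) / den
    max(min(d, 0.5), -0.5)
  }
  df1 <- spec$f1_axis[2] - spec$f1_axis[1]
  df2 <- spec$f2_axis[2] - spec$f2_axis[1]
  n <- nrow(cand)
  f1 <- f2 <- numeric(n)
  for (t in seq_len(n)) {
    i <- cand[t, 1]; j <- cand[t, 2]
    d1 <- if (i > 1L && i < n1) refine(m[i - 1L, j], m[i, j], m[i + 1L, j]) else 0
    d2 <- if (j > 1L && j < n2) refine(m[i, j - 1L], m[i, j], m[i, j + 1L]) else 0
    f1[t] <- spec$f1_axis[i] + d1 * df1
    f2[t] <- spec$f2_axis[j] + d2 * df2
  }
  out <- data.frame(
    mz_prec = freq_to_mz(f1 + spec$f_min, spec$vertical_law),
    mz_frag = freq_to_mz(f2, spec$horizontal_law),
    f1 = f1, f2 = f2,
    row = cand[, 1], col = cand[, 2],
    intensity = m[cand], snr = snr)
  out <- out[order(-out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_peaks <- function() {
  data.frame(mz_prec = numeric(0), mz_frag = numeric(0),
             f1 = numeric(0), f2 = numeric(0),
             row = integer(0), col = integer(0),
             intensity = numeric(0), snr = numeric(0))
}
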