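# Ion cyclotron physics and axis calibration for both dimensions of a 2D
# FT-ICR experiment with quadrupolar (2-omega) detection.

#' Instrument configuration for a 2D FT-ICR experiment
#'
#' Describes the acquisition geometry of a two-dimensional FT-ICR
#' measurement: magnetic field, excited m/z range, encoding-delay sampling
#' (the vertical precursor dimension) and transient sampling (the horizontal
#' fragment dimension), and the detection harmonic (1 for dipolar detection,
#' 2 for quadrupolar detection).
#'
#' @param magnetic_field Magnetic field in tesla.
#' @param mz_max Highest excited m/z (Th); sets the fundamental frequency
#'   `f_min` of the encoding dimension.
#' @param mz_min_frag Lowest fragment m/z excited/detected (Th).
#' @param delta_t1 Encoding-delay increment in seconds.
#' @param n_t1 Number of encoding steps (power of two).
#' @param n_t2 Samples per transient (power of two).
#' @param t2_duration Transient duration in seconds.
#' @param detection_harmonic Detection harmonic, 1 or 2.
#' @return An object of class `instrument_config`.
#' @examples
#' cfg <- instrument_config(12, 3000, 196.51, 3e-6, 4096, 2^20, 0.559, 2L)
#' @export
instrument_config <- function(magnetic_field, mz_max, mz_min_frag,
                              delta_t1, n_t1, n_t2, t2_duration,
                              detection_harmonic = 2L) {
  stopifnot(is.numeric(magnetic_field), magnetic_field > 0)
  if (!(mz_min_frag > 0 && mz_min_frag < mz_max))
    stop("require 0 < mz_min_frag < mz_max")
  if (delta_t1 <= 0) stop("delta_t1 must be positive")
  if (t2_duration <= 0) stop("t2_duration must be positive")
  .check_pow2 <- function(n, what) {
    n <- as.integer(n)
    if (n < 2L || bitwAnd(n, n - 1L) != 0L)
      stop(what, " must be a power of two (got ", n, ")")
    n
  }
  detection_harmonic <- as.integer(detection_harmonic)
  if (!detection_harmonic %in% c(1L, 2L))
    stop("detection_harmonic must be 1 or 2")
  structure(list(
    magnetic_field = magnetic_field,
    mz_max = mz_max,
    mz_min_frag = mz_min_frag,
    delta_t1 = delta_t1,
    n_t1 = .check_pow2(n_t1, "n_t1"),
    n_t2 = .check_pow2(n_t2, "n_t2"),
    t2_duration = t2_duration,
    detection_harmonic = detection_harmonic
  ), class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf(
    "<instrument_config> B = %g T, m/z %g-%g, harmonic %d\n  t1: %d x %g s, t2: %d pts / %g s\n",
    x$magnetic_field, x$mz_min_frag, x$mz_max, x$detection_harmonic,
    x$n_t1, x$delta_t1, x$n_t2, x$t2_duration))
  invisible(x)
}

#' Quadratic frequency-to-m/z calibration law
#'
#' Frequency and m/z are related by `f = a/mz + b/mz^2`. The ideal one-term
#' coefficient is `a = harmonic * 1.535611e7 * B` Hz Th; the quadratic
#' correction `b` defaults to zero.
#'
#' @param magnetic_field Magnetic field in tesla (used when `coeff_a` is not
#'   given).
#' @param harmonic Detection harmonic the law describes (1 or 2).
#' @param coeff_a Linear coefficient in Hz Th; default
#'   `harmonic * 1.535611e7 * magnetic_field`.
#' @param coeff_b Quadratic coefficient in Hz Th^2 (default 0).
#' @return An object of class `calibration_law`.
#' @examples
#' law <- calibration_law(12)            # 1-omega law at 12 T
#' mz_to_freq(3000, law)                 # ~61.4 kHz
#' @export
calibration_law <- function(magnetic_field = NULL, harmonic = 1L,
                            coeff_a = NULL, coeff_b = 0) {
  harmonic <- as.integer(harmonic)
  if (!harmonic %in% c(1L, 2L)) stop("harmonic must be 1 or 2")
  if (is.null(coeff_a)) {
    if (is.null(magnetic_field))
      stop("supply either magnetic_field or coeff_a")
    coeff_a <- harmonic * .ICR_CAL_K * magnetic_field
  }
  if (coeff_a <= 0) stop("coeff_a must be positive")
  structure(list(coeff_a = coeff_a, coeff_b = coeff_b, harmonic = harmonic),
            class = "calibration_law")
}

#' @export
print.calibration_law <- function(x, ...) {
  cat(sprintf("<calibration_law> f = %.6g/mz + %.6g/mz^2 (harmonic %d)\n",
              x$coeff_a, x$coeff_b, x$harmonic))
  invisible(x)
}

#' Convert m/z to detected frequency
#'
#' @param mz m/z values in Th (positive).
#' @param law A [calibration_law()].
#' @return Frequencies in Hz.
#' @export
mz_to_freq <- function(mz, law) {
  stopifnot(inherits(law, "calibration_law"))
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("mz must be positive and finite")
  law$coeff_a / mz + law$coeff_b / mz^2
}

#' Convert detected frequency to m/z (inverse of the quadratic law)
#'
#' With `coeff_b = 0` this is `coeff_a / f`; otherwise the quadratic
#' `b/m^2 + a/m - f = 0` is solved for the physical (positive) root.
#'
#' @param freq Frequencies in Hz (positive, within the invertible range).
#' @param law A [calibration_law()].
#' @return m/z values in Th.
#' @export
freq_to_mz <- function(freq, law) {
  stopifnot(inherits(law, "calibration_law"))
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("freq must be positive and finite (domain error)")
  if (law$coeff_b == 0) {
    law$coeff_a / freq
  } else {
    disc <- law$coeff_a^2 + 4 * law$coeff_b * freq
    if (any(disc < 0)) stop("frequency outside invertible range of the law")
    u <- 2 * freq / (law$coeff_a + sqrt(disc))  # u = 1/mz, stable form
    if (any(u <= 0)) stop("frequency outside invertible range of the law")
    1 / u
  }
}

#' Rescale a calibration law to another detection harmonic
#'
#' Under quadrupolar (2-omega) detection the conversion coefficients are
#' doubled relative to fundamental detection; this multiplies both
#' coefficients by `h / law$harmonic`.
#'
#' @param law A [calibration_law()].
#' @param h Target harmonic (1 or 2).
#' @return A [calibration_law()] at harmonic `h`.
#' @export
scale_to_harmonic <- function(law, h) {
  stopifnot(inherits(law, "calibration_law"))
  h <- as.integer(h)
  if (!h %in% c(1L, 2L)) stop("unsupported harmonic: ", h)
  s <- h / law$harmonic
  calibration_law(harmonic = h, coeff_a = law$coeff_a * s,
                  coeff_b = law$coeff_b * s)
}

#' Nyquist bandwidth of the encoding (vertical) dimension
#'
#' @param delta_t1 Encoding increment in seconds.
#' @return Bandwidth `1 / (2 * delta_t1)` in Hz.
#' @examples
#' encoding_bandwidth(3e-6)  # 166667 Hz
#' @export
encoding_bandwidth <- function(delta_t1) {
  if (any(!is.finite(delta_t1)) || any(delta_t1 <= 0))
    stop("delta_t1 must be positive")
  1 / (2 * delta_t1)
}

## fundamental (1-omega) law of a configuration and its digital modulation
## floor f_min (the 1-omega cyclotron frequency of mz_max)
.fundamental_law <- function(config) {
  calibration_law(config$magnetic_field, harmonic = 1L)
}

.f_min <- function(config) {
  mz_to_freq(config$mz_max, .fundamental_law(config))
}

#' Modulation frequency of a precursor ion
#'
#' The encoding dimension modulates each precursor at
#' `f_ICR(mz) - f_min`, where `f_ICR` is the fundamental cyclotron
#' frequency and `f_min` the digital modulation floor set at the
#' fundamental frequency of the highest excited m/z.
#'
#' @param mz Precursor m/z (Th), at most `config$mz_max`.
#' @param config An [instrument_config()].
#' @return Modulation frequency in Hz (nonnegative, strictly decreasing
#'   in m/z).
#' @export
modulation_frequency <- function(mz, config) {
  stopifnot(inherits(config, "instrument_config"))
  if (any(mz > config$mz_max))
    stop("mz exceeds config$mz_max (out of range)")
  law1 <- .fundamental_law(config)
  mz_to_freq(mz, law1) - .f_min(config)
}

#' Precursor m/z range addressable by the encoding dimension
#'
#' The upper bound is the highest excited m/z; the lower bound is the m/z
#' whose fundamental cyclotron frequency equals the encoding Nyquist
#' bandwidth plus the digital modulation floor `f_min`.
#'
#' @param config An [instrument_config()].
#' @return Named numeric vector `c(lower, upper)` in Th.
#' @examples
#' cfg <- instrument_config(12, 3000, 196.51, 3e-6, 4096, 2^20, 0.559, 2L)
#' precursor_mz_range(cfg)  # lower bound ~808
#' @export
precursor_mz_range <- function(config) {
  stopifnot(inherits(config, "instrument_config"))
  law1 <- .fundamental_law(config)
  f_hi <- encoding_bandwidth(config$delta_t1) + .f_min(config)
  c(lower = freq_to_mz(f_hi, law1), upper = config$mz_max)
}

#' Calibration law of the horizontal (fragment) axis
#' @param config An [instrument_config()].
#' @return A [calibration_law()] at the configured detection harmonic.
#' @export
horizontal_law <- function(config) {
  stopifnot(inherits(config, "instrument_config"))
  calibration_law(config$magnetic_field, harmonic = config$detection_harmonic)
}
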