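# Forward model for 2D FT-ICR transients: encoding-delay amplitude
# modulation of precursors, anti-modulated fragment and electron-capture
# products, nonsinusoidal modulation harmonics, scintillation noise and
# 1-omega leakage under quadrupolar detection.

#' m/z of the singly charge-reduced electron-capture product
#'
#' Capture of one electron by an `n+` precursor yields an `(n-1)+` ion at
#' `mz * n / (n - 1)` (electron mass neglected).
#'
#' @param precursor_mz Precursor m/z in Th.
#' @param charge Precursor charge (at least 2; a singly charged precursor
#'   would give a neutral product).
#' @return m/z of the charge-reduced species in Th.
#' @examples
#' capture_product_mz(874, 10)  # 971.1
#' @export
capture_product_mz <- function(precursor_mz, charge) {
  charge <- as.integer(charge)
  if (any(charge < 2L))
    stop("charge must be >= 2 (product would be neutral)")
  precursor_mz * charge / (charge - 1L)
}

#' Precursor channel for the 2D forward model
#'
#' One modulated precursor species together with its dissociation products.
#' Fragment yields and the electron-capture yield are fractions of the
#' modulated precursor population; their sum plus the surviving fraction
#' equals one.
#'
#' @param mz Precursor m/z (Th).
#' @param charge Precursor charge state.
#' @param abundance Relative abundance (arbitrary units).
#' @param fragments `data.frame` with columns `mz`, `yield` and optionally
#'   `charge` (default 1) for the ECD products of this precursor.
#' @param capture_yield Fraction undergoing electron capture without
#'   dissociation (charge-reduced product).
#' @param pattern Optional [isotope_pattern()] of the precursor; when
#'   present, every isotopologue is modulated at its own frequency and
#'   fragment isotopologues are drawn by binomial transfer.
#' @param label Optional channel label.
#' @return Object of class `precursor_channel`.
#' @export
precursor_channel <- function(mz, charge, abundance = 1, fragments = NULL,
                              capture_yield = 0, pattern = NULL,
                              label = NULL) {
  charge <- as.integer(charge)
  stopifnot(mz > 0, charge >= 1L, abundance >= 0)
  if (is.null(fragments)) {
    fragments <- data.frame(mz = numeric(0), yield = numeric(0),
                            charge = integer(0))
  } else {
    stopifnot(is.data.frame(fragments), all(c("mz", "yield") %in%
                                              names(fragments)))
    if (is.null(fragments$charge)) fragments$charge <- 1L
  }
  tot <- sum(fragments$yield) + capture_yield
  if (capture_yield < 0 || any(fragments$yield < 0) || tot > 1 + 1e-9)
    stop("fragment yields + capture_yield must be fractions summing to <= 1")
  structure(list(mz = mz, charge = charge, abundance = abundance,
                 fragments = fragments, capture_yield = capture_yield,
                 pattern = pattern, label = label),
            class = "precursor_channel")
}

#' Noise and modulation-shape model for the 2D forward model
#'
#' @param thermal_sigma Standard deviation of additive detector noise
#'   (signal units).
#' @param scintillation_cv Coefficient of variation of the multiplicative
#'   scan-to-scan (per-t1-row) ion-number fluctuation.
#' @param leakage_1w Fractional leakage of the fundamental (1-omega) signal
#'   into a quadrupolar (2-omega) detection channel; produces duplicate
#'   lines at half the detected frequency.
#' @param harmonic_weights Amplitudes of the overtones added to the base
#'   cosine of the precursor modulation (nonsinusoidal modulation).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(thermal_sigma = 0, scintillation_cv = 0,
                        leakage_1w = 0, harmonic_weights = c(0.2, 0.05)) {
  stopifnot(thermal_sigma >= 0,
            scintillation_cv >= 0, scintillation_cv < 1,
            leakage_1w >= 0, leakage_1w < 1,
            all(is.finite(harmonic_weights)))
  structure(list(thermal_sigma = thermal_sigma,
                 scintillation_cv = scintillation_cv,
                 leakage_1w = leakage_1w,
                 harmonic_weights = harmonic_weights),
            class = "noise_model")
}

#' Simulate a two-dimensional FT-ICR transient
#'
#' For each encoding step `k` the precursor of each channel is modulated at
#' its modulation frequency `f_mod`: its surviving detected amplitude
#' follows the nonsinusoidal waveform `cos(phi) + sum_j w_j cos((j+1) phi)`
#' (with `phi = 2 pi f_mod k delta_t1`) scaled by the unfragmented
#' fraction, while fragment and electron-capture products are
#' anti-modulated through the on-axis overlap `exp(-(r/r0)^2)` with
#' normalized radius r equal to the magnitude of cos(phi/2) (ions return to the cell axis once
#' per modulation period, where radius-dependent ECD is most efficient).
#' Every species contributes a decaying cosine along t2 at its
#' detection-harmonic frequency plus, under 2-omega detection, a
#' `leakage_1w`-weighted cosine at the fundamental. Each t1 row is scaled
#' by an independent multiplicative scintillation factor and thermal noise
#' is added everywhere.
#'
#' @param config An [instrument_config()].
#' @param channels List of [precursor_channel()] objects.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the transient is fully reproducible from it.
#' @param r0 Normalized on-axis overlap radius of the fragmentation
#'   efficiency model (default 0.8).
#' @return Object of class `transient2d`: list with the `n_t1 x n_t2` real
#'   matrix `data`, the `config`, the `seed` and the channel list.
#' @export
simulate_transient2d <- function(config, channels, noise = noise_model(),
                                 seed = 1L, r0 = 0.8) {
  stopifnot(inherits(config, "instrument_config"),
            inherits(noise, "noise_model"))
  if (inherits(channels, "precursor_channel")) channels <- list(channels)
  rng_mz <- precursor_mz_range(config)
  law1 <- .fundamental_law(config)
  lawH <- horizontal_law(config)
  fmin <- .f_min(config)
  fs2 <- config$n_t2 / config$t2_duration
  dt2 <- 1 / fs2
  t2 <- (0:(config$n_t2 - 1L)) * dt2
  k1 <- 0:(config$n_t1 - 1L)
  T2 <- config$t2_duration
  decay <- exp(-t2 / T2)
  leak <- noise$leakage_1w
  use_leak <- leak > 0 && config$detection_harmonic == 2L
  cosline <- function(mz_line) {
    f2 <- mz_to_freq(mz_line, lawH)
    if (f2 >= fs2 / 2)
      stop("species at m/z ", signif(mz_line, 8),
           " exceeds the t2 Nyquist frequency")
    x <- cos(2 * pi * f2 * t2)
    if (use_leak) x <- x + leak * cos(pi * f2 * t2)
    x * decay
  }
  data <- matrix(0, config$n_t1, config$n_t2)
  for (ch in channels) {
    stopifnot(inherits(ch, "precursor_channel"))
    if (ch$mz < rng_mz[["lower"]] - 1e-9 || ch$mz > rng_mz[["upper"]] + 1e-9)
      stop("precursor m/z ", signif(ch$mz, 8),
           " outside precursor_mz_range(config)")
    if (nrow(ch$fragments) &&
        (any(ch$fragments$mz < config$mz_min_frag) ||
         any(ch$fragments$mz > config$mz_max)))
      stop("fragment m/z outside [mz_min_frag, mz_max]")
    iso <- ch$pattern
    if (is.null(iso)) iso <- data.frame(mz = ch$mz, rel_abundance = 1)
    frag_budget <- sum(ch$fragments$yield) + ch$capture_yield
    for (i in seq_len(nrow(iso))) {
      mz_i <- iso$mz[i]
      a_i <- iso$rel_abundance[i]
      dn_i <- as.integer(round((mz_i - iso$mz[1]) * ch$charge /
                                 .NEUTRON_SPACING))
      fmod <- max(mz_to_freq(mz_i, law1) - fmin, 0)
      phi <- 2 * pi * fmod * k1 * config$delta_t1
      eff <- exp(-(cos(phi / 2) / r0)^2)       # on-axis overlap
      wave <- cos(phi)
      for (j in seq_along(noise$harmonic_weights))
        wave <- wave + noise$harmonic_weights[j] * cos((j + 1) * phi)
      env_prec <- (1 - frag_budget * eff) * wave
      x_prec <- a_i * ch$abundance * ch$charge * cosline(mz_i)
      data <- data + tcrossprod(env_prec, x_prec)
      ## products of this isotopologue share the overlap envelope
      x_prod <- numeric(config$n_t2)
      if (nrow(ch$fragments)) {
        for (f in seq_len(nrow(ch$fragments))) {
          fz <- ch$fragments$charge[f]
          ## binomial transfer of the precursor's extra neutrons
          p_tr <- min((ch$fragments$mz[f] * fz) / (mz_i * ch$charge), 0.999)
          for (j in 0:dn_i) {
            w <- stats::dbinom(j, dn_i, p_tr)
            if (w < 1e-3) next
            x_prod <- x_prod + ch$abundance * ch$fragments$yield[f] * a_i *
              w * fz * cosline(ch$fragments$mz[f] + j * .NEUTRON_SPACING / fz)
          }
        }
      }
      if (ch$capture_yield > 0 && ch$charge >= 2L) {
        x_prod <- x_prod + ch$abundance * ch$capture_yield *
          (ch$charge - 1L) * a_i * cosline(capture_product_mz(mz_i, ch$charge))
      }
      if (any(x_prod != 0)) data <- data + tcrossprod(eff, x_prod)
    }
  }
  set.seed(as.integer(seed))
  if (noise$scintillation_cv > 0) {
    scint <- 1 + noise$scintillation_cv * stats::rnorm(config$n_t1)
    data <- data * scint
  }
  if (noise$thermal_sigma > 0)
    data <- data + matrix(stats::rnorm(length(data), sd = noise$thermal_sigma),
                          nrow(data), ncol(data))
  structure(list(data = data, config = config, seed = as.integer(seed),
                 channels = channels, noise = noise, r0 = r0),
            class = "transient2d")
}

#' @export
print.transient2d <- function(x, ...) {
  cat(sprintf("<transient2d> %d x %d, %d channel(s), seed %d\n",
              nrow(x$data), ncol(x$data), length(x$channels), x$seed))
  invisible(x)
}

## Poisson-binomial distribution of the total modification count over
## independent sites with occupancy probabilities p; returns P(total = n)
## for n = 0..length(p)
.poisson_binomial <- function(p) {
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  dist
}

## P(sum over sites in `subset` = j | total over all sites = n)
.conditional_span_counts <- function(p, subset, n) {
  stopifnot(n <= length(p))
  p_in <- p[subset]
  p_out <- p[setdiff(seq_along(p), subset)]
  d_in <- .poisson_binomial(p_in)    # length length(subset)+1
  d_out <- .poisson_binomial(p_out)
  num <- numeric(length(p_in) + 1L)
  for (j in 0:length(p_in)) {
    rest <- n - j
    if (rest >= 0 && rest <= length(p_out))
      num[j + 1L] <- d_in[j + 1L] * d_out[rest + 1L]
  }
  tot <- sum(num)
  if (tot == 0) return(num)
  num / tot
}

#' Acetylated-ubiquitin scenario for the 2D forward model
#'
#' Builds a realistic multi-proteoform scenario: ubiquitin charge states
#' (default 7-10+) carrying a range of acetylation counts, with c- and
#' z-fragment channels whose yields encode the supplied per-site occupancy
#' probabilities exactly (via the conditional span-count distribution given
#' the proteoform's total modification count). The ground truth used to
#' derive every yield is returned alongside the channels.
#'
#' @param occupancy Numeric vector of site-occupancy probabilities in
#'   `[0, 1]`, one per candidate acetylation site of ubiquitin (M1, K6,
#'   K11, K27, K29, K33, K48, K63), optionally named by residue index.
#' @param charge_states Integer vector of precursor charge states.
#' @param n_mods Integer vector of total acetylation counts to include.
#' @param c_indices,z_indices Ladder indices of the simulated c and z
#'   fragment channels.
#' @param capture_yield Electron-capture yield per channel.
#' @param fragment_budget Total fragment yield distributed over the ladder.
#' @param isotopes Logical; attach isotope patterns to the precursors
#'   (heavier to simulate, exercises envelope-summation logic).
#' @param config Optional [instrument_config()]; a default sized for the
#'   scenario is built when omitted.
#' @param seed Integer seed recorded in the output.
#' @return List with elements `config`, `channels` and `truth` (occupancy
#'   vector, conditional per-site occupation probabilities for each total
#'   count, and the channel table).
#' @export
ubiquitin_fixture <- function(occupancy, charge_states = 7:10,
                              n_mods = 4:6,
                              c_indices = c(2, 5, 6, 10, 11, 26, 27, 28, 29,
                                            32, 33, 47, 48, 62, 63, 75),
                              z_indices = c(13, 14, 28, 29, 43, 44, 47, 48,
                                            49, 50, 65, 66, 70, 71, 75),
                              capture_yield = 0.1, fragment_budget = 0.6,
                              isotopes = FALSE, config = NULL, seed = 1L) {
  seq <- protein_sequence(ubiquitin_sequence())
  spec <- acetyl_spec()
  sites <- candidate_sites(seq, spec)
  if (length(occupancy) != length(sites))
    stop("occupancy must have one value per candidate site (",
         length(sites), ")")
  if (any(occupancy < 0 | occupancy > 1))
    stop("occupancies must be in [0, 1]")
  occupancy <- stats::setNames(as.numeric(occupancy), as.character(sites))
  tot_dist <- .poisson_binomial(occupancy)
  if (all(tot_dist[n_mods + 1L] <= 0))
    stop("occupancies are inconsistent with the requested n_mods range")
  if (is.null(config))
    config <- instrument_config(
      magnetic_field = 12, mz_max = 3000, mz_min_frag = 250,
      delta_t1 = 3e-6, n_t1 = 512L, n_t2 = 4096L,
      t2_duration = 4096 / 3.2e6, detection_harmonic = 2L)
  len <- length(residues(seq))
  n_ladder <- length(c_indices) + length(z_indices)
  eff <- fragment_budget / n_ladder
  channels <- list()
  truth_rows <- list()
  cond <- list()
  for (n in n_mods) {
    pn <- tot_dist[n + 1L]
    if (pn <= 0) next
    ## conditional per-site occupation probability given total = n
    q <- vapply(seq_along(sites), function(s)
      sum(.conditional_span_counts(occupancy, s, n) * 0:1), numeric(1))
    cond[[as.character(n)]] <- stats::setNames(q, as.character(sites))
    for (z in charge_states) {
      ## higher acetylation shifts the charge distribution down
      zw <- exp(-((z - (max(charge_states) - 0.7 * (n - min(n_mods))))^2) / 2)
      abund <- pn * zw
      frows <- list()
      for (i in c_indices) {
        span_sites <- which(sites %in% .fragment_span("c", i, len))
        qj <- .conditional_span_counts(occupancy, span_sites, n)
        for (j in seq_along(qj) - 1L) {
          if (qj[j + 1L] < 1e-6) next
          m <- fragment_neutral_mass(seq, "c", i, j, spec)
          fz <- max(1L, ceiling((m + 1) / (config$mz_max - 50)))
          frows[[length(frows) + 1L]] <- data.frame(
            series = "c", index = i, n_frag_mods = j, charge = fz,
            mz = (m + fz * .PROTON_MASS) / fz, yield = eff * qj[j + 1L])
        }
      }
      for (i in z_indices) {
        span_sites <- which(sites %in% .fragment_span("z", i, len))
        qj <- .conditional_span_counts(occupancy, span_sites, n)
        for (j in seq_along(qj) - 1L) {
          if (qj[j + 1L] < 1e-6) next
          m <- fragment_neutral_mass(seq, "z", i, j, spec)
          fz <- max(1L, ceiling((m + 1) / (config$mz_max - 50)))
          frows[[length(frows) + 1L]] <- data.frame(
            series = "z", index = i, n_frag_mods = j, charge = fz,
            mz = (m + fz * .PROTON_MASS) / fz, yield = eff * qj[j + 1L])
        }
      }
      ftab <- do.call(rbind, frows)
      keep <- ftab$mz >= config$mz_min_frag & ftab$mz <= config$mz_max
      ftab <- ftab[keep, , drop = FALSE]
      pmz <- precursor_mz(seq, spec, n, z)
      pat <- NULL
      if (isotopes)
        pat <- isotope_pattern(precursor_formula(seq, spec, n, z),
                               charge = z, prune = 0.2)
      channels[[length(channels) + 1L]] <- precursor_channel(
        mz = pmz, charge = z, abundance = abund,
        fragments = ftab[, c("mz", "yield", "charge")],
        capture_yield = if (z >= 2) capture_yield else 0,
        pattern = pat,
        label = sprintf("[M+%dH+%dAc]%d+", z, n, z))
      truth_rows[[length(truth_rows) + 1L]] <- cbind(
        data.frame(precursor_mz = pmz, charge = z, n_mods = n,
                   abundance = abund), ftab)
    }
  }
  list(config = config, channels = channels,
       truth = list(occupancy = occupancy,
                    conditional_site_prob = cond,
                    total_dist = tot_dist,
                    table = do.call(rbind, truth_rows),
                    seed = as.integer(seed)))
}
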