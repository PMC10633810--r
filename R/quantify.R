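# Fragment assignment, cleavage coverage, per-site modification-occupancy
# profiles and average-charge statistics.

#' Match picked peaks against a theoretical fragment library
#'
#' Each peak is assigned to the nearest library ion within `tol_ppm`; ties
#' are broken by smaller absolute ppm error, then by lower modification
#' count, and remaining exact ties are flagged ambiguous. With
#' `isotope_check = TRUE` the full predicted isotopologue envelope is
#' correlated with the scan and a cosine similarity of at least
#' `pattern_threshold` is required.
#'
#' @param peaks `data.frame` with columns `mz` and `intensity` (e.g. from
#'   [pick_peaks_1d()]).
#' @param library Fragment library from [build_library()] (or any
#'   `data.frame` with `series`, `index`, `charge`, `n_mods`, `mz`, and
#'   `formula` when the isotope check is on).
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @param isotope_check Require an envelope cosine check against `scan`.
#' @param scan The `scan1d` the peaks were picked from (needed for the
#'   isotope check).
#' @param pattern_threshold Minimum envelope cosine (default 0.9).
#' @return `data.frame` of assignments: `peak_mz`, `intensity`, `series`,
#'   `index`, `charge`, `n_mods`, `mz_theo`, `ppm_error`, `pattern_score`,
#'   `ambiguous`.
#' @export
match_fragments <- function(peaks, library, tol_ppm = 5,
                            isotope_check = FALSE, scan = NULL,
                            pattern_threshold = 0.9) {
  if (is.null(library) || !nrow(library)) stop("library must be nonempty")
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  if (isotope_check && is.null(scan))
    stop("isotope_check requires the source scan")
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    pmz <- peaks$mz[i]
    ppm <- (pmz - library$mz) / library$mz * 1e6
    cand <- which(abs(ppm) <= tol_ppm)
    if (!length(cand)) next
    o <- cand[order(abs(ppm[cand]), library$n_mods[cand])]
    best <- o[1]
    ambiguous <- length(o) > 1 &&
      abs(abs(ppm[o[2]]) - abs(ppm[best])) < 1e-9 &&
      library$n_mods[o[2]] == library$n_mods[best]
    score <- NA_real_
    if (isotope_check) {
      pat <- isotope_pattern(library$formula[best],
                             charge = library$charge[best], prune = 0.02)
      obs <- stats::approx(scan$axis, scan$intensity, xout = pat$mz,
                           rule = 1)$y
      obs[is.na(obs)] <- 0
      denom <- sqrt(sum(pat$rel_abundance^2) * sum(obs^2))
      score <- if (denom > 0) sum(pat$rel_abundance * obs) / denom else 0
      if (score < pattern_threshold) next
    }
    out[[length(out) + 1L]] <- data.frame(
      peak_mz = pmz, intensity = peaks$intensity[i],
      series = library$series[best], index = library$index[best],
      charge = library$charge[best], n_mods = library$n_mods[best],
      mz_theo = library$mz[best], ppm_error = ppm[best],
      pattern_score = score, ambiguous = ambiguous,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peak_mz = numeric(0), intensity = numeric(0),
                      series = character(0), index = integer(0),
                      charge = integer(0), n_mods = integer(0),
                      mz_theo = numeric(0), ppm_error = numeric(0),
                      pattern_score = numeric(0), ambiguous = logical(0)))
  do.call(rbind, out)
}

#' Cleavage (sequence) coverage of a set of fragment assignments
#'
#' The fraction of inter-residue bonds evidenced by at least one assigned
#' N-terminal (a/b/c, bond = index) or C-terminal (y/z, bond = length -
#' index) fragment, as a percentage. Passing assignments pooled over
#' several charge states yields the union coverage.
#'
#' @param assignments `data.frame` with columns `series` and `index` (as
#'   returned by [match_fragments()]).
#' @param seq The [protein_sequence()].
#' @return Coverage percentage in `[0, 100]`.
#' @export
sequence_coverage <- function(assignments, seq) {
  len <- length(residues(protein_sequence(seq)))
  if (!nrow(assignments)) return(0)
  nterm <- assignments$series %in% c("a", "b", "c")
  bonds <- ifelse(nterm, assignments$index, len - assignments$index)
  bonds <- unique(bonds[bonds >= 1 & bonds <= len - 1])
  100 * length(bonds) / (len - 1)
}

## weighted pool-adjacent-violators: nondecreasing fit of y with weights w
.pava <- function(y, w) {
  n <- length(y)
  ys <- y; ws <- w; idx <- as.list(seq_len(n))
  i <- 1L
  while (i < length(ys)) {
    if (ys[i] > ys[i + 1L] + 1e-12) {
      wsum <- ws[i] + ws[i + 1L]
      ys[i] <- (ys[i] * ws[i] + ys[i + 1L] * ws[i + 1L]) / wsum
      ws[i] <- wsum
      idx[[i]] <- c(idx[[i]], idx[[i + 1L]])
      ys <- ys[-(i + 1L)]; ws <- ws[-(i + 1L)]; idx[-(i + 1L)] -> idx
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  out <- numeric(n)
  for (b in seq_along(ys)) out[idx[[b]]] <- ys[b]
  out
}

#' Per-site modification-occupancy profile from a fragment ladder
#'
#' For one proteoform (fixed total modification count `n_mods`) and one
#' ion series, the intensity-weighted mean modification count
#' `A(i) = sum_j j I(i, j) / sum_j I(i, j)` is computed for every observed
#' ladder index, made nondecreasing by weighted isotonic regression, and
#' anchored at the intact protein (`A = n_mods` for the complete ladder).
#' The per-site rate is the increase of `A` across each candidate site;
#' increases spanning several unresolved sites are distributed uniformly
#' among them, so the rates sum to `n_mods` by construction.
#'
#' @param assignments Assignments of a single proteoform from
#'   [match_fragments()] (columns `series`, `index`, `n_mods`,
#'   `intensity`); charge states may be pooled.
#' @param seq The [protein_sequence()].
#' @param spec The [mod_spec()].
#' @param n_mods Total modification count of the proteoform.
#' @param series `"c"` (or another N-terminal series) or `"z"`/`"y"`.
#' @return `data.frame` of class `occupancy_profile` with columns `site`
#'   (residue index), `residue`, `rate`; attributes `series`, `n_mods`
#'   and `cumulative` (the regularized ladder).
#' @export
acetylation_profile <- function(assignments, seq, spec = acetyl_spec(),
                                n_mods, series = "c") {
  seq <- protein_sequence(seq)
  len <- length(residues(seq))
  sites <- candidate_sites(seq, spec)
  series <- match.arg(series, c("a", "b", "c", "y", "z"))
  sel <- assignments[assignments$series == series, , drop = FALSE]
  if (!nrow(sel)) stop("no assignments for series '", series,
                       "' (empty profile)")
  ## aggregate intensity by (ladder index, fragment mod count)
  agg <- stats::aggregate(intensity ~ index + n_mods, data = sel, FUN = sum)
  idxs <- sort(unique(agg$index))
  A <- Wt <- numeric(length(idxs))
  for (t in seq_along(idxs)) {
    rows <- agg$index == idxs[t]
    Wt[t] <- sum(agg$intensity[rows])
    A[t] <- sum(agg$n_mods[rows] * agg$intensity[rows]) / Wt[t]
  }
  A <- .pava(A, Wt)
  A <- pmin(pmax(A, 0), n_mods)
  ## anchor: the complete ladder (the intact chain) carries n_mods
  idxs <- c(idxs, len)
  A <- c(A, n_mods)
  ## map ladder indices to the highest covered site position
  ## N-terminal series: index i covers residues 1..i
  ## C-terminal series: index i covers residues len-i+1..len
  rate <- stats::setNames(numeric(length(sites)), as.character(sites))
  a_prev <- 0; i_prev <- 0L
  for (t in seq_along(idxs)) {
    i_cur <- idxs[t]
    if (series %in% c("a", "b", "c")) {
      span_sites <- sites[sites > i_prev & sites <= i_cur]
    } else {
      ## z_i covers sites s with s >= len - i + 1
      span_sites <- sites[sites >= len - i_cur + 1L &
                            (i_prev == 0L | sites < len - i_prev + 1L)]
    }
    d <- A[t] - a_prev
    if (d > 0 && length(span_sites)) {
      rate[as.character(span_sites)] <-
        rate[as.character(span_sites)] + d / length(span_sites)
    } else if (d > 0 && !length(span_sites)) {
      if (t < length(idxs)) {
        ## no candidate site in this span: carry the increase forward
        A[t] <- a_prev
        next
      }
      ## residual at the intact-protein anchor with no uncovered site left:
      ## spread it uniformly so the rates still sum to n_mods
      rate <- rate + d / length(rate)
    }
    a_prev <- A[t]; i_prev <- i_cur
  }
  out <- data.frame(site = sites,
                    residue = residues(seq)[sites],
                    rate = as.numeric(rate[as.character(sites)]))
  attr(out, "series") <- series
  attr(out, "n_mods") <- n_mods
  attr(out, "cumulative") <- data.frame(index = idxs, A = A)
  class(out) <- c("occupancy_profile", "data.frame")
  out
}

#' Rank candidate sites by mean occupancy across profiles
#'
#' @param profiles A single `occupancy_profile` or a list of them (e.g. c-
#'   and z-series profiles across modification counts).
#' @param tie_tol Rates closer than this are considered tied.
#' @return `data.frame` with `site`, `residue`, `mean_rate`, `rank`,
#'   `tied`, ordered by decreasing mean rate.
#' @export
site_ranking <- function(profiles, tie_tol = 1e-6) {
  if (inherits(profiles, "occupancy_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("at least one profile is required")
  sites <- profiles[[1]]$site
  rates <- sapply(profiles, function(p) {
    stopifnot(identical(p$site, sites))
    p$rate
  })
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = length(sites))
  mr <- rowMeans(rates)
  o <- order(-mr, sites)
  out <- data.frame(site = sites[o], residue = profiles[[1]]$residue[o],
                    mean_rate = mr[o], rank = seq_along(o))
  d <- c(Inf, abs(diff(out$mean_rate)))
  out$tied <- d < tie_tol | c(d[-1] < tie_tol, FALSE)
  out
}

#' Abundance-weighted average charge state per modification count
#'
#' FT-ICR intensities are proportional to abundance times charge, so the
#' abundance-weighted mean charge of the `I(z, n)` intensity table is
#' `<z>(n) = sum_z I(z, n) / sum_z I(z, n) / z`.
#'
#' @param intensities Numeric matrix of intensities with one row per
#'   charge state and one column per modification count, or a numeric
#'   vector for a single count.
#' @param charges Charge states corresponding to the rows (defaults to
#'   integer rownames / names).
#' @return Numeric vector of average charge states, one per column.
#' @examples
#' average_charge(c(`10` = 10, `8` = 8))  # 9: equal abundances at 10+/8+
#' @export
average_charge <- function(intensities, charges = NULL) {
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, ncol = 1,
                          dimnames = list(names(intensities), NULL))
  if (is.null(charges)) {
    if (is.null(rownames(intensities)))
      stop("supply charges or name the rows with charge states")
    charges <- as.numeric(rownames(intensities))
  }
  stopifnot(length(charges) == nrow(intensities), all(charges >= 1))
  apply(intensities, 2, function(I) {
    if (all(I <= 0)) stop("all-zero intensity column: <z> undefined")
    sum(I) / sum(I / charges)
  })
}
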