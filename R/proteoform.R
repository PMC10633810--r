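# Sequence, modification, fragment-mass and isotope-pattern arithmetic for
# variably modified proteins (the theoretical-library side of the workflow).

#' Protein sequence
#'
#' @param x Single string of one-letter amino-acid codes (canonical 20),
#'   length at least 2. Residues are indexed 1-based from the N-terminus.
#' @return Character scalar of class `protein_sequence`.
#' @examples
#' ubi <- protein_sequence(ubiquitin_sequence())
#' @export
protein_sequence <- function(x) {
  if (inherits(x, "protein_sequence")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(gsub("[[:space:]]", "", x))
  res <- strsplit(x, "")[[1]]
  if (length(res) < 2L) stop("sequence must have at least 2 residues")
  bad <- setdiff(unique(res), .AA_LETTERS)
  if (length(bad))
    stop("non-canonical residue letter(s): ", paste(bad, collapse = ", "))
  structure(x, class = c("protein_sequence", "character"))
}

#' Residue letters of a protein sequence
#' @param seq A [protein_sequence()] (or coercible string).
#' @return Character vector of one-letter codes, 1-based positions.
#' @export
residues <- function(seq) {
  strsplit(unclass(protein_sequence(seq)), "")[[1]]
}

#' The 76-residue ubiquitin sequence
#' @return Character scalar (canonical human ubiquitin).
#' @export
ubiquitin_sequence <- function() {
  paste0("MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYN",
         "IQKESTLHLVLRLRGG")
}

#' Variable-modification specification
#'
#' @param name Modification name.
#' @param delta_composition Elemental composition added per modification
#'   (named vector or formula string); acetylation is `C2H2O`
#'   (+42.010565 Da).
#' @param targets Residue letters that can carry the modification.
#' @param nterm Residue letters for which position 1 is additionally a
#'   candidate site (the N-terminal amine); `character(0)` disables the
#'   N-terminus, `TRUE` allows any residue at position 1.
#' @param min_count,max_count Bounds on the number of modifications per
#'   proteoform.
#' @return Object of class `mod_spec` with the delta mass precomputed.
#' @examples
#' acetyl_spec()
#' @export
mod_spec <- function(name, delta_composition, targets, nterm = character(0),
                     min_count = 0L, max_count = 8L) {
  delta_composition <- as_formula(delta_composition)
  min_count <- as.integer(min_count); max_count <- as.integer(max_count)
  if (!(max_count >= min_count && min_count >= 0L))
    stop("require max_count >= min_count >= 0")
  dm <- formula_mass(delta_composition)
  if (dm <= -min(.RESIDUE_MASS))
    stop("delta mass must exceed minus the smallest residue mass")
  structure(list(name = name, delta_composition = delta_composition,
                 delta_mass = dm, targets = toupper(targets),
                 nterm = if (isTRUE(nterm)) TRUE else toupper(nterm),
                 min_count = min_count, max_count = max_count),
            class = "mod_spec")
}

#' Acetylation specification (K side chains plus the N-terminal M)
#' @param min_count,max_count Modification-count bounds (defaults 0 and 8).
#' @return A [mod_spec()] for +42.010565 Da acetylation.
#' @export
acetyl_spec <- function(min_count = 0L, max_count = 8L) {
  mod_spec("acetyl", c(C = 2, H = 2, O = 1), targets = "K", nterm = "M",
           min_count = min_count, max_count = max_count)
}

#' Candidate modification sites of a sequence
#'
#' All residues matching the target letters, plus residue 1 when the
#' N-terminus rule of the specification matches the first residue.
#'
#' @param seq A [protein_sequence()].
#' @param spec A [mod_spec()].
#' @return Sorted integer vector of 1-based residue indices.
#' @examples
#' candidate_sites(protein_sequence(ubiquitin_sequence()), acetyl_spec())
#' @export
candidate_sites <- function(seq, spec) {
  stopifnot(inherits(spec, "mod_spec"))
  res <- residues(seq)
  idx <- which(res %in% spec$targets)
  ntm <- if (isTRUE(spec$nterm)) TRUE else res[1] %in% spec$nterm
  if (ntm) idx <- union(idx, 1L)
  sort(unique(as.integer(idx)))
}

## residue span covered by a fragment
.fragment_span <- function(series, index, len) {
  if (series %in% c("a", "b", "c")) seq_len(index) else (len - index + 1L):len
}

#' Elemental composition of a fragment ion (neutral + charging protons)
#'
#' @param seq A [protein_sequence()].
#' @param series Ion series, one of `"a","b","c","y","z"` (`z` is the
#'   z-dot radical).
#' @param index Cleavage index, 1 to length-1.
#' @param charge Positive charge count (protons, included as H in the
#'   composition; the electron mass is neglected).
#' @param n_mods Number of variable modifications carried.
#' @param spec A [mod_spec()].
#' @return Named integer vector of element counts.
#' @export
fragment_formula <- function(seq, series, index, charge = 1L, n_mods = 0L,
                             spec = acetyl_spec()) {
  seq <- protein_sequence(seq); res <- residues(seq); len <- length(res)
  series <- match.arg(series, c("a", "b", "c", "y", "z"))
  index <- as.integer(index)
  if (index < 1L || index > len - 1L)
    stop("index must be in 1..length-1")
  if (charge < 1L) stop("charge must be >= 1")
  span <- .fragment_span(series, index, len)
  n_sites <- sum(candidate_sites(seq, spec) %in% span)
  if (n_mods < 0L || n_mods > n_sites)
    stop("n_mods (", n_mods, ") not achievable: fragment span has ",
         n_sites, " candidate site(s)")
  comp <- colSums(.RESIDUE_COMP[res[span], , drop = FALSE])
  comp <- .add_formulas(comp, .SERIES_DELTA[[series]])
  if (n_mods > 0L)
    comp <- .add_formulas(comp, spec$delta_composition * n_mods)
  .add_formulas(comp, c(H = as.integer(charge)))
}

#' Neutral monoisotopic mass of a fragment
#' @inheritParams fragment_formula
#' @return Mass in Da.
#' @export
fragment_neutral_mass <- function(seq, series, index, n_mods = 0L,
                                  spec = acetyl_spec()) {
  f <- fragment_formula(seq, series, index, charge = 1L, n_mods = n_mods,
                        spec = spec)
  formula_mass(f) - .ELEMENT_MONO[["H"]]
}

#' Monoisotopic m/z of a fragment ion
#'
#' Ion-type conventions: `c` = N-terminal residue sum + NH3;
#' `z` = z-dot radical = y - 16.018724 Da; `y` = C-terminal residue sum +
#' H2O; `a`/`b` as usual. Protonation adds 1.00727646 Da per charge.
#'
#' @inheritParams fragment_formula
#' @return m/z in Th.
#' @examples
#' ubi <- protein_sequence(ubiquitin_sequence())
#' fragment_mz(ubi, "c", 3, 1)                 # 390.2170
#' fragment_mz(ubi, "c", 3, 1, n_mods = 1)     # 432.2275
#' @export
fragment_mz <- function(seq, series, index, charge = 1L, n_mods = 0L,
                        spec = acetyl_spec()) {
  m <- fragment_neutral_mass(seq, series, index, n_mods, spec)
  (m + charge * .PROTON_MASS) / charge
}

#' Neutral monoisotopic mass and m/z of an intact proteoform
#'
#' @param seq A [protein_sequence()].
#' @param spec A [mod_spec()].
#' @param n_mods Number of modifications carried.
#' @param charge Positive charge (for [precursor_mz()]).
#' @return Mass in Da / m/z in Th.
#' @export
precursor_neutral_mass <- function(seq, spec = acetyl_spec(), n_mods = 0L) {
  res <- residues(protein_sequence(seq))
  sum(.RESIDUE_MASS[res]) + formula_mass(.WATER) + n_mods * spec$delta_mass
}

#' @rdname precursor_neutral_mass
#' @export
precursor_mz <- function(seq, spec = acetyl_spec(), n_mods = 0L, charge = 1L) {
  if (charge < 1L) stop("charge must be >= 1")
  (precursor_neutral_mass(seq, spec, n_mods) + charge * .PROTON_MASS) / charge
}

#' Elemental composition of an intact proteoform (neutral + protons)
#' @inheritParams precursor_neutral_mass
#' @param charge Number of charging protons to include as H.
#' @return Named integer vector of element counts.
#' @export
precursor_formula <- function(seq, spec = acetyl_spec(), n_mods = 0L,
                              charge = 0L) {
  res <- residues(protein_sequence(seq))
  comp <- colSums(.RESIDUE_COMP[res, , drop = FALSE])
  comp <- .add_formulas(comp, .WATER, c(H = as.integer(charge)))
  if (n_mods > 0L)
    comp <- .add_formulas(comp, spec$delta_composition * n_mods)
  comp
}

#' Theoretical fragment-ion library
#'
#' Enumerates every (series, index, charge, n_mods) combination whose
#' modification count is achievable given the candidate sites inside the
#' fragment span, computes monoisotopic m/z, and returns the library sorted
#' by m/z.
#'
#' @param seq A [protein_sequence()].
#' @param spec A [mod_spec()].
#' @param series Character vector of ion series to generate.
#' @param charges Integer vector of fragment charges.
#' @param n_mods_range Length-2 integer vector, inclusive bounds on the
#'   modification count per fragment (additionally capped by the number of
#'   candidate sites in the span).
#' @return `data.frame` with columns `series`, `index`, `charge`, `n_mods`,
#'   `mz`, `formula`.
#' @examples
#' lib <- build_library(protein_sequence("MKAAK"), acetyl_spec(),
#'                      series = "c", charges = 1L, n_mods_range = c(0, 2))
#' @export
build_library <- function(seq, spec = acetyl_spec(),
                          series = c("c", "z", "y"), charges = 1L,
                          n_mods_range = c(0L, 0L)) {
  seq <- protein_sequence(seq)
  if (!length(series)) stop("series set must be nonempty")
  series <- match.arg(series, c("a", "b", "c", "y", "z"), several.ok = TRUE)
  len <- length(residues(seq))
  sites <- candidate_sites(seq, spec)
  rows <- list()
  for (s in series) for (i in seq_len(len - 1L)) {
    span <- .fragment_span(s, i, len)
    n_sites <- sum(sites %in% span)
    lo <- max(min(n_mods_range), 0L)
    hi <- min(max(n_mods_range), n_sites)
    if (lo > hi) next
    for (z in as.integer(charges)) for (m in lo:hi) {
      f <- fragment_formula(seq, s, i, z, m, spec)
      rows[[length(rows) + 1L]] <- data.frame(
        series = s, index = i, charge = z, n_mods = m,
        mz = (formula_mass(f) - z * (.ELEMENT_MONO[["H"]] - .PROTON_MASS)) / z,
        formula = formula_string(f),
        stringsAsFactors = FALSE)
    }
  }
  lib <- do.call(rbind, rows)
  lib <- unique(lib)
  lib[order(lib$mz), , drop = FALSE]
}

#' Isotopologue pattern of an elemental formula
#'
#' Computes the aggregated isotopologue distribution by element-wise
#' polynomial convolution over the extra-neutron index, using the natural
#' isotope abundances of C, H, N, O and S. Adjacent isotopologues are
#' spaced by approximately `1.0033548 / charge` Th; each aggregated peak
#' carries its abundance-weighted mean m/z. The distribution is normalized
#' to its most abundant peak and pruned below `prune`.
#'
#' @param formula Elemental formula (named vector or string); for an ion,
#'   include the charging protons as H.
#' @param charge Positive charge used to convert mass to m/z (protons are
#'   assumed; the electron mass is neglected).
#' @param prune Relative-abundance threshold in `[0, 1)` below which peaks
#'   are dropped.
#' @return `data.frame` with columns `mz` (strictly increasing) and
#'   `rel_abundance` (max = 1), of class `isotope_pattern`.
#' @examples
#' isotope_pattern(c(C = 100), charge = 1)
#' @export
isotope_pattern <- function(formula, charge = 1L, prune = 1e-4) {
  formula <- as_formula(formula)
  if (all(formula == 0)) stop("formula must be nonempty")
  if (any(formula < 0)) stop("formula counts must be nonnegative here")
  if (charge < 1L) stop("charge must be >= 1")
  if (prune < 0 || prune >= 1) stop("prune must be in [0, 1)")
  ## distribution over extra neutrons: p[k+1] = probability of k extra
  ## neutrons, msum[k+1] = sum of probability * mass in that bin
  one <- function(el) {
    iso <- .ISOTOPES[[el]]
    n <- max(iso$dn)
    p <- numeric(n + 1); ms <- numeric(n + 1)
    p[iso$dn + 1L] <- iso$abundance
    ms[iso$dn + 1L] <- iso$abundance * iso$mass
    list(p = p, ms = ms)
  }
  cnv <- function(a, b) {
    na <- length(a$p); nb <- length(b$p)
    p <- numeric(na + nb - 1L); ms <- numeric(na + nb - 1L)
    ma <- ifelse(a$p > 0, a$ms / a$p, 0)
    mb <- ifelse(b$p > 0, b$ms / b$p, 0)
    for (i in seq_len(na)) {
      if (a$p[i] == 0) next
      j <- seq_len(nb)
      p[i + j - 1L] <- p[i + j - 1L] + a$p[i] * b$p
      ms[i + j - 1L] <- ms[i + j - 1L] + a$p[i] * b$p * (ma[i] + mb)
    }
    ## prune vanishing tail to keep the convolution short
    keep <- which(p > 1e-15)
    if (length(keep)) {
      hi <- max(keep)
      p <- p[seq_len(hi)]; ms <- ms[seq_len(hi)]
    }
    list(p = p, ms = ms)
  }
  ## exponentiation by squaring per element
  total <- list(p = 1, ms = 0)
  for (el in names(formula)) {
    n <- formula[[el]]
    if (n == 0) next
    base <- one(el)
    while (n > 0) {
      if (n %% 2 == 1) total <- cnv(total, base)
      n <- n %/% 2
      if (n > 0) base <- cnv(base, base)
    }
  }
  mass <- ifelse(total$p > 0, total$ms / total$p, NA_real_)
  keep <- total$p > 0
  p <- total$p[keep]; mass <- mass[keep]
  rel <- p / max(p)
  keep <- rel >= max(prune, 1e-12)
  mass <- mass[keep]; rel <- rel[keep]
  ## the formula already contains the charging protons as H atoms; convert
  ## to m/z by removing the electron-free correction (neglected) and
  ## dividing by charge
  mz <- (mass - charge * (.ELEMENT_MONO[["H"]] - .PROTON_MASS)) / charge
  structure(data.frame(mz = mz, rel_abundance = rel),
            class = c("isotope_pattern", "data.frame"))
}
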