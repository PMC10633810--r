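# Elemental and amino-acid mass data shared across the package.
# All monoisotopic masses are derived from the isotope table below so that
# residue masses, fragment masses and isotope patterns come from one source.

## fundamental constants
.PROTON_MASS <- 1.00727646    # Da, mass of H+ (electron mass excluded)
.NEUTRON_SPACING <- 1.0033548 # Da, average isotopologue spacing (13C - 12C)
.ICR_CAL_K <- 1.535611e7      # Hz * Th / T, one-term cyclotron calibration constant

## isotope table: per element, masses (Da) and natural abundances,
## ordered by increasing neutron count relative to the lightest isotope
.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.00335484),
           abundance = c(0.9893, 0.0107),
           dn = c(0L, 1L)),
  H = list(mass = c(1.00782503207, 2.01410177785),
           abundance = c(0.999885, 0.000115),
           dn = c(0L, 1L)),
  N = list(mass = c(14.0030740048, 15.0001088982),
           abundance = c(0.99636, 0.00364),
           dn = c(0L, 1L)),
  O = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
           abundance = c(0.99757, 0.00038, 0.00205),
           dn = c(0L, 1L, 2L)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001),
           dn = c(0L, 1L, 2L, 4L))
)

## residue elemental compositions (residue = amino acid - H2O), canonical 20
.RESIDUE_COMP <- rbind(
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0)
)

.AA_LETTERS <- rownames(.RESIDUE_COMP)

## monoisotopic mass of one atom of each element (lightest isotope)
.ELEMENT_MONO <- vapply(.ISOTOPES, function(el) el$mass[1], numeric(1))

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Named integer vector of element counts (names among
#'   C, H, N, O, S; negative counts are allowed for composition deltas),
#'   or a formula string such as `"C2H2O"`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(c(C = 2, H = 2, O = 1))  # acetylation delta, 42.010565
#' @export
formula_mass <- function(formula) {
  formula <- as_formula(formula)
  sum(.ELEMENT_MONO[names(formula)] * formula)
}

#' Coerce a formula string or named vector to a canonical count vector
#'
#' @param formula Named numeric vector or string like `"C16H31N5O4S"`.
#' @return Named integer vector over the supported elements (C, H, N, O, S).
#' @export
as_formula <- function(formula) {
  if (is.character(formula)) {
    stopifnot(length(formula) == 1L)
    parts <- regmatches(formula,
                        gregexpr("[A-Z][a-z]?-?[0-9]*", formula))[[1]]
    parts <- parts[nzchar(parts)]
    out <- integer(0)
    for (p in parts) {
      el <- gsub("[-0-9]", "", p)
      n <- gsub("[A-Za-z]", "", p)
      n <- if (nzchar(n)) as.integer(n) else 1L
      out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
    }
    formula <- out
  }
  if (is.null(names(formula)) || any(!nzchar(names(formula))))
    stop("formula must be a named vector or a formula string")
  bad <- setdiff(names(formula), names(.ISOTOPES))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  out <- stats::setNames(integer(length(.ISOTOPES)), names(.ISOTOPES))
  out[names(formula)] <- as.integer(round(formula))
  out
}

#' Format an element count vector as a formula string
#' @param formula Named integer vector of element counts.
#' @return Character scalar, e.g. `"C16H31N5O4S"`; elements with zero count
#'   are dropped.
#' @export
formula_string <- function(formula) {
  formula <- as_formula(formula)
  formula <- formula[formula != 0]
  paste0(names(formula),
         ifelse(formula == 1, "", as.character(formula)),
         collapse = "")
}

.add_formulas <- function(...) {
  out <- stats::setNames(integer(length(.ISOTOPES)), names(.ISOTOPES))
  for (f in list(...)) {
    f <- as_formula(f)
    out[names(f)] <- out[names(f)] + f
  }
  out
}

## derived composition deltas for ion series (neutral species), relative to
## the plain residue sum of the covered span:
##   b : nothing          a : b - CO
##   c : b + NH3          y : residue sum + H2O
##   z : z-dot radical, y - NH3 + H  (composition delta O +1, N -1)
.SERIES_DELTA <- list(
  a = c(C = -1, O = -1),
  b = c(C = 0),
  c = c(N = 1, H = 3),
  y = c(H = 2, O = 1),
  z = c(N = -1, O = 1)
)

.WATER <- c(H = 2, O = 1)

.RESIDUE_MASS <- local({
  m <- numeric(nrow(.RESIDUE_COMP))
  for (i in seq_along(m))
    m[i] <- sum(.ELEMENT_MONO * .RESIDUE_COMP[i, names(.ELEMENT_MONO)])
  stats::setNames(m, .AA_LETTERS)
})
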