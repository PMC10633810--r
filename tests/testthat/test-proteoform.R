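# Sequence/modification arithmetic, fragment masses, libraries and
# isotope patterns. Frozen expected masses were computed independently
# from a standard residue/isotope mass table.

test_that("candidate acetylation sites follow the target + N-terminus rule", {
  sites <- candidate_sites(ubi_seq(), acetyl_spec())
  expect_identical(sites, c(1L, 6L, 11L, 27L, 29L, 33L, 48L, 63L))
  expect_length(sites, 8L)
  expect_identical(candidate_sites(protein_sequence("AAAA"), acetyl_spec()),
                   integer(0))
  expect_identical(candidate_sites(protein_sequence("MKA"), acetyl_spec()),
                   c(1L, 2L))
})

test_that("fragment m/z matches independently computed ECD ion masses", {
  ubi <- ubi_seq()
  # c3 (M-Q-I + NH3 + H+) and its acetylated form
  expect_equal(fragment_mz(ubi, "c", 3, 1), 390.216952, tolerance = 2e-6)
  expect_equal(fragment_mz(ubi, "c", 3, 1, n_mods = 1), 432.227517,
               tolerance = 2e-6)
  # y1 of a sequence ending in G
  expect_equal(fragment_mz(protein_sequence("AG"), "y", 1, 1), 76.03930,
               tolerance = 1e-6)
  # z-dot sits 16.018724 below y at every cleavage
  for (i in c(5, 40, 70))
    expect_equal(fragment_neutral_mass(ubi, "z", i),
                 fragment_neutral_mass(ubi, "y", i) - 16.018724,
                 tolerance = 1e-7)
  expect_error(fragment_mz(ubi, "c", 76, 1), "index")
})

test_that("c/z pairs covering one cleavage sum to precursor + fixed offset", {
  ubi <- ubi_seq()
  M <- precursor_neutral_mass(ubi)
  offs <- vapply(seq(1, 75, by = 6), function(i)
    fragment_neutral_mass(ubi, "c", i) +
      fragment_neutral_mass(ubi, "z", 76 - i) - M, numeric(1))
  expect_equal(offs, rep(offs[1], length(offs)), tolerance = 1e-9)
  expect_equal(offs[1], 1.0078250, tolerance = 1e-6)  # one H (z-dot + c)
})

test_that("one modification shifts containing fragments by 42.010565/z", {
  ubi <- ubi_seq()
  for (z in c(1L, 2L, 3L)) {
    d <- fragment_mz(ubi, "c", 30, z, n_mods = 2) -
      fragment_mz(ubi, "c", 30, z, n_mods = 1)
    expect_equal(d, 42.010565 / z, tolerance = 1e-7)
  }
  expect_equal(precursor_mz(ubi, acetyl_spec(), 5, 10) -
                 precursor_mz(ubi, acetyl_spec(), 4, 10),
               4.2010565, tolerance = 1e-7)
})

test_that("precursor masses are computed from the sequence", {
  ubi <- ubi_seq()
  expect_equal(precursor_neutral_mass(ubi), 8559.61671, tolerance = 1e-7)
  expect_equal(precursor_mz(protein_sequence("AG"), n_mods = 0, charge = 1),
               147.076415, tolerance = 1e-6)
  # [M + 10H + 4Ac]10+ sits near the m/z 874 autocorrelation species
  expect_equal(precursor_mz(ubi, acetyl_spec(), 4, 10), 873.7732,
               tolerance = 1e-6)
})

test_that("library enumeration is span-constrained, sorted, duplicate-free", {
  lib5 <- build_library(protein_sequence("ACDEG"), acetyl_spec(),
                        series = "c", charges = 1L, n_mods_range = c(0, 0))
  expect_identical(nrow(lib5), 4L)  # length - 1 cleavages
  libu <- build_library(ubi_seq(), acetyl_spec(), series = "c",
                        charges = 1L, n_mods_range = c(0, 0))
  expect_identical(nrow(libu), 75L)
  # "MK": c1 spans only the N-terminal M -> at most one acetyl on c1
  libmk <- build_library(protein_sequence("MK"), acetyl_spec(),
                         series = "c", charges = 1L, n_mods_range = c(0, 2))
  expect_identical(sort(libmk$n_mods[libmk$index == 1]), c(0L, 1L))
  # sorted by m/z, unique keys, deterministic
  expect_true(!is.unsorted(libmk$mz))
  lib2 <- build_library(ubi_seq(), acetyl_spec(), series = c("c", "z"),
                        charges = 1:2, n_mods_range = c(0, 2))
  key <- with(lib2, paste(series, index, charge, n_mods))
  expect_identical(anyDuplicated(key), 0L)
  expect_true(!is.unsorted(lib2$mz))
  expect_identical(lib2, build_library(ubi_seq(), acetyl_spec(),
                                       series = c("c", "z"), charges = 1:2,
                                       n_mods_range = c(0, 2)))
  expect_error(fragment_formula(ubi_seq(), "c", 3, 1, n_mods = 3),
               "not achievable")
})

test_that("isotope patterns match elementwise-convolution reference values", {
  # single carbon: M+1/M equals the 13C/12C abundance ratio
  pc <- isotope_pattern(c(C = 1))
  expect_equal(pc$rel_abundance[2] / pc$rel_abundance[1], 0.0108157,
               tolerance = 1e-4)
  # H2 with the deuterated form pruned: a single peak
  expect_identical(nrow(isotope_pattern(c(H = 2), prune = 1e-3)), 1L)
  # C100: M+1/M ~ 100 x single-atom ratio
  p100 <- isotope_pattern(c(C = 100))
  expect_equal(p100$rel_abundance[2] / p100$rel_abundance[1], 1.08157,
               tolerance = 1e-3)
  # protonated ubiquitin c3 (C16 H32 N5 O4 S): frozen reference envelope
  p3 <- isotope_pattern(c(C = 16, H = 32, N = 5, O = 4, S = 1))
  expect_equal(p3$rel_abundance[1:3], c(1, 0.204418, 0.072854),
               tolerance = 1e-3)
  expect_error(isotope_pattern(c(Xx = 2)), "unknown element")
})

test_that("isotope patterns are normalized, increasing, charge-spaced", {
  for (z in c(1L, 2L, 5L)) {
    f <- precursor_formula(ubi_seq(), acetyl_spec(), 4, charge = z)
    p <- isotope_pattern(f, charge = z, prune = 0.01)
    expect_equal(max(p$rel_abundance), 1)
    expect_true(all(p$rel_abundance > 0 & p$rel_abundance <= 1))
    expect_true(all(diff(p$mz) > 0))
    expect_equal(diff(p$mz), rep(1.00336 / z, nrow(p) - 1), tolerance = 2e-3)
  }
})

test_that("sequences and modification specs validate their inputs", {
  expect_error(protein_sequence("MXK"), "non-canonical")
  expect_error(protein_sequence("A"), "at least 2")
  expect_error(mod_spec("x", c(C = 1), "K", min_count = 2, max_count = 1),
               "min_count")
  s <- acetyl_spec()
  expect_equal(s$delta_mass, 42.010565, tolerance = 1e-7)
})
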