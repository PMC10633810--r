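# Run configuration (JSON/YAML) and the staged pipeline driver.

#' Default run configuration
#'
#' A small acetylated-ubiquitin demonstration: one charge state, two
#' proteoforms, mild thermal noise, magnitude-mode processing and c/z
#' fragment quantification.
#'
#' @return Nested list with blocks `instrument`, `calibration`,
#'   `simulation`, `processing`, `quantification`.
#' @export
default_run_config <- function() {
  list(
    instrument = list(magnetic_field = 12, mz_max = 3000, mz_min_frag = 250,
                      delta_t1 = 3e-6, n_t1 = 512L, n_t2 = 4096L,
                      t2_duration = 4096 / 3.2e6, detection_harmonic = 2L),
    calibration = list(coeff_b = 0),
    simulation = list(
      seed = 1L, fixture = "ubiquitin",
      occupancy = c(0.7, 0.8, 0.35, 0.4, 0.45, 0.6, 0.9, 0.95),
      charge_states = c(8L, 9L), n_mods = c(4L, 5L), isotopes = FALSE,
      noise = list(thermal_sigma = 0.02, scintillation_cv = 0,
                   leakage_1w = 0, harmonic_weights = c(0.2, 0.05))),
    processing = list(beta = 6, zerofill = 1L, rank = NULL,
                      snr_threshold = 5, rank_seed = 1L),
    quantification = list(tol_ppm = 400, series = c("c", "z"),
                          n_adjacent = 5L, snr_threshold = 5)
  )
}

.cfg_check <- function(cond, field, msg) {
  if (!cond) stop("config error at '", field, "': ", msg, call. = FALSE)
}

#' Validate a run configuration
#'
#' Checks types, ranges and cross-field consistency; errors name the
#' offending field path.
#'
#' @param config Nested configuration list.
#' @return The validated configuration (with integer fields coerced),
#'   invisibly usable downstream.
#' @export
validate_run_config <- function(config) {
  .cfg_check(is.list(config), "(root)", "must be a list/object")
  for (blk in c("instrument", "simulation", "processing", "quantification"))
    .cfg_check(is.list(config[[blk]]), blk, "block is missing")
  ins <- config$instrument
  for (f in c("magnetic_field", "mz_max", "mz_min_frag", "delta_t1",
              "n_t1", "n_t2", "t2_duration"))
    .cfg_check(is.numeric(ins[[f]]) && length(ins[[f]]) == 1L &&
                 ins[[f]] > 0, paste0("instrument.", f),
               "must be a positive number")
  .cfg_check(!is.null(ins$detection_harmonic) &&
               ins$detection_harmonic %in% c(1, 2),
             "instrument.detection_harmonic", "must be 1 or 2")
  sim <- config$simulation
  .cfg_check(is.numeric(sim$seed) && length(sim$seed) == 1L,
             "simulation.seed", "a seed is mandatory for simulation")
  if (!is.null(sim$fixture)) {
    .cfg_check(identical(sim$fixture, "ubiquitin"), "simulation.fixture",
               "only 'ubiquitin' is available")
    .cfg_check(is.numeric(sim$occupancy) && length(sim$occupancy) == 8L &&
                 all(sim$occupancy >= 0 & sim$occupancy <= 1),
               "simulation.occupancy",
               "must be 8 site probabilities in [0, 1]")
    .cfg_check(is.numeric(sim$charge_states) && all(sim$charge_states >= 1),
               "simulation.charge_states", "must be positive integers")
    .cfg_check(is.numeric(sim$n_mods) && all(sim$n_mods >= 0),
               "simulation.n_mods", "must be nonnegative integers")
  } else {
    .cfg_check(is.list(sim$channels) && length(sim$channels) > 0,
               "simulation.channels",
               "supply either a fixture or explicit channels")
  }
  if (!is.null(sim$noise)) {
    nz <- sim$noise
    for (f in c("thermal_sigma", "scintillation_cv", "leakage_1w"))
      if (!is.null(nz[[f]]))
        .cfg_check(is.numeric(nz[[f]]) && nz[[f]] >= 0,
                   paste0("simulation.noise.", f), "must be >= 0")
  }
  prc <- config$processing
  if (!is.null(prc$beta))
    .cfg_check(is.numeric(prc$beta) && prc$beta >= 0, "processing.beta",
               "must be >= 0")
  if (!is.null(prc$zerofill))
    .cfg_check(is.numeric(prc$zerofill) && prc$zerofill >= 0,
               "processing.zerofill", "must be a nonnegative integer")
  if (!is.null(prc$rank) && !is.na(prc$rank))
    .cfg_check(is.numeric(prc$rank) && prc$rank >= 1, "processing.rank",
               "must be >= 1")
  .cfg_check(is.numeric(prc$snr_threshold) && prc$snr_threshold > 0,
             "processing.snr_threshold", "must be positive")
  qnt <- config$quantification
  .cfg_check(is.numeric(qnt$tol_ppm) && qnt$tol_ppm > 0,
             "quantification.tol_ppm", "must be positive")
  if (!is.null(qnt$n_adjacent))
    .cfg_check(qnt$n_adjacent >= 1 && qnt$n_adjacent %% 2 == 1,
               "quantification.n_adjacent", "must be odd and >= 1")
  ## instrument block is additionally validated by its constructor
  do.call(instrument_config, ins)
  invisible(config)
}

#' Read a run configuration from JSON or YAML
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  validate_run_config(config)
  config
}

.build_scenario <- function(config, seed) {
  ins <- config$instrument
  icfg <- do.call(instrument_config, ins)
  sim <- config$simulation
  nz <- sim$noise
  noise <- noise_model(
    thermal_sigma = if (is.null(nz$thermal_sigma)) 0 else nz$thermal_sigma,
    scintillation_cv = if (is.null(nz$scintillation_cv)) 0 else
      nz$scintillation_cv,
    leakage_1w = if (is.null(nz$leakage_1w)) 0 else nz$leakage_1w,
    harmonic_weights = if (is.null(nz$harmonic_weights)) c(0.2, 0.05) else
      nz$harmonic_weights)
  if (!is.null(sim$fixture)) {
    fx <- ubiquitin_fixture(occupancy = sim$occupancy,
                            charge_states = as.integer(sim$charge_states),
                            n_mods = as.integer(sim$n_mods),
                            isotopes = isTRUE(sim$isotopes),
                            config = icfg, seed = seed)
    list(config = icfg, channels = fx$channels, truth = fx$truth,
         noise = noise)
  } else {
    chans <- lapply(sim$channels, function(ch)
      precursor_channel(mz = ch$mz, charge = ch$charge,
                        abundance = if (is.null(ch$abundance)) 1 else
                          ch$abundance,
                        fragments = if (is.null(ch$fragments)) NULL else
                          as.data.frame(ch$fragments),
                        capture_yield = if (is.null(ch$capture_yield)) 0 else
                          ch$capture_yield))
    list(config = icfg, channels = chans, truth = NULL, noise = noise)
  }
}

#' Run the 2D MS pipeline
#'
#' Chains the stages `simulate` (forward model), `process` (apodization,
#' zero filling, 2D FT, optional denoising, peak picking), `extract`
#' (autocorrelation line and per-precursor fragment scans), `assign`
#' (library matching of scan peaks) and `quantify` (coverage, occupancy
#' profiles, average charge). Later stages read the artifacts written by
#' earlier ones from `out_dir`, so stages can be re-run individually.
#'
#' @param config Configuration list (see [default_run_config()]) or a path
#'   accepted by [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stage One of `"simulate"`, `"process"`, `"extract"`, `"assign"`,
#'   `"quantify"`, `"all"`.
#' @param seed Optional seed overriding `config$simulation$seed`.
#' @param quiet Suppress progress messages.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stage = "all", seed = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  stage <- match.arg(stage, c("all", "simulate", "process", "extract",
                              "assign", "quantify"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- as.integer(config$simulation$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  p <- function(f) file.path(out_dir, f)
  paths <- list(transient = p("transient.rds"), spectrum = p("spectrum.rds"),
                peaks = p("peaks2d.csv"), autocorrelation = p("autocorrelation.csv"),
                truth = p("truth.rds"), assignments = p("assignments.csv"),
                profiles = p("profiles.csv"), summary = p("summary.json"))
  stages <- if (stage == "all")
    c("simulate", "process", "extract", "assign", "quantify") else stage

  if ("simulate" %in% stages) {
    sc <- .build_scenario(config, seed)
    say("simulate: %d channel(s), %d x %d transient, seed %d",
        length(sc$channels), sc$config$n_t1, sc$config$n_t2, seed)
    tr <- simulate_transient2d(sc$config, sc$channels, sc$noise, seed = seed)
    save_dataset(tr, paths$transient)
    saveRDS(sc["truth"], paths$truth)
  }
  if ("process" %in% stages) {
    tr <- load_dataset(paths$transient)
    prc <- config$processing
    beta <- if (is.null(prc$beta)) 6 else prc$beta
    zf <- if (is.null(prc$zerofill)) 1L else as.integer(prc$zerofill)
    rank <- prc$rank
    if (!is.null(rank) && (is.na(rank) || rank < 1)) rank <- NULL
    say("process: Kaiser beta=%g, zerofill %d, rank %s", beta, zf,
        if (is.null(rank)) "none" else rank)
    tr <- apodize_kaiser(tr, beta = beta)
    tr <- zerofill(tr, factor = zf)
    spec <- ft2d_magnitude(tr, rank = rank,
                           rank_seed = if (is.null(prc$rank_seed)) 1L else
                             as.integer(prc$rank_seed))
    save_dataset(spec, paths$spectrum)
    pk <- peak_pick_2d(spec, snr_threshold = prc$snr_threshold)
    pk <- flag_artifacts(pk, spec)
    write_table_csv(pk, paths$peaks)
  }
  if ("extract" %in% stages) {
    spec <- load_dataset(paths$spectrum)
    write_scan_csv(autocorrelation_line(spec), paths$autocorrelation)
    truth <- readRDS(paths$truth)$truth
    if (!is.null(truth)) {
      prows <- unique(truth$table[, c("precursor_mz", "charge", "n_mods")])
      nadj <- config$quantification$n_adjacent
      if (is.null(nadj)) nadj <- 5L
      for (r in seq_len(nrow(prows))) {
        sc1 <- fragment_scan(spec, prows$precursor_mz[r], nadj)
        write_scan_csv(sc1, p(sprintf("fragment_scan_z%d_n%d.csv",
                                      prows$charge[r], prows$n_mods[r])))
      }
      say("extract: autocorrelation + %d fragment scan(s)", nrow(prows))
    }
  }
  if ("assign" %in% stages) {
    spec <- load_dataset(paths$spectrum)
    truth <- readRDS(paths$truth)$truth
    qnt <- config$quantification
    seq <- protein_sequence(ubiquitin_sequence())
    spx <- acetyl_spec()
    lib <- build_library(seq, spx, series = qnt$series,
                         charges = 1:3,
                         n_mods_range = c(0L, max(config$simulation$n_mods)))
    rows <- list()
    if (!is.null(truth)) {
      prows <- unique(truth$table[, c("precursor_mz", "charge", "n_mods")])
      nadj <- if (is.null(qnt$n_adjacent)) 5L else qnt$n_adjacent
      for (r in seq_len(nrow(prows))) {
        sc1 <- fragment_scan(spec, prows$precursor_mz[r], nadj)
        pk1 <- pick_peaks_1d(sc1, snr_threshold = qnt$snr_threshold)
        if (!nrow(pk1)) next
        asg <- match_fragments(pk1, lib, tol_ppm = qnt$tol_ppm)
        if (!nrow(asg)) next
        asg$precursor_charge <- prows$charge[r]
        asg$proteoform_n_mods <- prows$n_mods[r]
        rows[[length(rows) + 1L]] <- asg
      }
    }
    asg <- if (length(rows)) do.call(rbind, rows) else
      match_fragments(data.frame(mz = numeric(0), intensity = numeric(0)),
                      lib)
    say("assign: %d assignment(s)", nrow(asg))
    write_table_csv(asg, paths$assignments)
  }
  if ("quantify" %in% stages) {
    asg <- utils::read.csv(paths$assignments)
    truth <- readRDS(paths$truth)$truth
    qnt <- config$quantification
    seq <- protein_sequence(ubiquitin_sequence())
    spx <- acetyl_spec()
    summary <- list()
    profs <- list()
    if (nrow(asg)) {
      cov_total <- sequence_coverage(asg, seq)
      covs <- lapply(split(asg, asg$proteoform_n_mods), function(d)
        list(n_mods = d$proteoform_n_mods[1],
             coverage_pct = sequence_coverage(d, seq)))
      summary$coverage <- list(total_pct = cov_total,
                               per_proteoform = unname(covs))
      for (n in sort(unique(asg$proteoform_n_mods)))
        for (sr in intersect(qnt$series, unique(asg$series))) {
          sub <- asg[asg$proteoform_n_mods == n, , drop = FALSE]
          pr <- tryCatch(acetylation_profile(sub, seq, spx, n_mods = n,
                                             series = sr),
                         error = function(e) NULL)
          if (is.null(pr)) next
          pr$series <- sr; pr$n_mods <- n
          profs[[length(profs) + 1L]] <- pr
        }
    }
    if (length(profs)) {
      ptab <- do.call(rbind, lapply(profs, as.data.frame))
      write_table_csv(ptab, paths$profiles)
      rk <- site_ranking(profs)
      summary$site_ranking <- rk
    }
    if (!is.null(truth)) {
      tab <- unique(truth$table[, c("charge", "n_mods", "abundance")])
      zs <- sort(unique(tab$charge)); ns <- sort(unique(tab$n_mods))
      I <- matrix(0, length(zs), length(ns), dimnames = list(zs, ns))
      for (r in seq_len(nrow(tab)))
        I[as.character(tab$charge[r]), as.character(tab$n_mods[r])] <-
          tab$abundance[r] * tab$charge[r]
      summary$average_charge <- as.list(stats::setNames(
        average_charge(I), paste0("n", ns)))
    }
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("quantify: summary written to %s", paths$summary)
  }
  invisible(paths)
}
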