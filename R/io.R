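# File I/O: FASTA sequences, dataset serialization, scan / peak / library
# CSV export with JSON metadata headers.

#' Read a protein sequence from a FASTA file
#'
#' The first record is parsed (a warning is issued when more records are
#' present); non-canonical residue letters are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_sequence()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  if (length(set) > 1L)
    warning("multiple FASTA records; using the first (",
            names(set)[1], ")")
  protein_sequence(as.character(set[[1]]))
}

.DATASET_FORMAT <- "icr2dms-dataset"
.DATASET_VERSION <- 1L

#' Save / load a transient or spectrum dataset
#'
#' Datasets are stored as versioned R serializations; arrays round-trip
#' bit-identically and calibration metadata is preserved. A version or
#' format mismatch is reported as an error.
#'
#' @param x A `transient2d` or `spectrum2d`.
#' @param path Destination / source path.
#' @return `save_dataset` returns `path` invisibly; `load_dataset` returns
#'   the restored object.
#' @export
save_dataset <- function(x, path) {
  stopifnot(inherits(x, "transient2d") || inherits(x, "spectrum2d"))
  saveRDS(list(format = .DATASET_FORMAT, version = .DATASET_VERSION,
               class = class(x), object = x), path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupted or unreadable dataset: ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, .DATASET_FORMAT))
    stop("not an icr2dms dataset: ", path)
  if (!identical(obj$version, .DATASET_VERSION))
    stop("dataset version mismatch: file has ", obj$version,
         ", this package reads ", .DATASET_VERSION)
  obj$object
}

#' Write a 1D scan as CSV with a JSON metadata header
#'
#' The first line is a `#`-prefixed JSON object holding the scan metadata
#' (kind, anchor m/z, rows summed); the body has columns `mz,intensity`.
#'
#' @param scan A `scan1d`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "scan1d"))
  meta <- jsonlite::toJSON(scan$meta, auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", meta), con)
  utils::write.table(data.frame(mz = scan$axis, intensity = scan$intensity),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scan written by [write_scan_csv()]
#' @param path Source path.
#' @return A `scan1d`.
#' @export
read_scan_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(kind = "unknown", anchor = NA_real_, rows_summed = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    meta <- jsonlite::fromJSON(sub("^#", "", first))
    skip <- 1L
  }
  d <- utils::read.csv(path, skip = skip)
  extra <- meta[setdiff(names(meta), c("kind", "anchor", "rows_summed"))]
  .scan1d(d$mz, d$intensity, kind = meta$kind,
          anchor = if (is.null(meta$anchor)) NA_real_ else meta$anchor,
          rows_summed = meta$rows_summed, extra = extra)
}

#' Write a fragment library or peak/assignment table as CSV
#' @param x A `data.frame`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
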