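#' Write a recording session to disk
#'
#' Serializes a [recording_session()] as a directory: `traces.bin` (float64
#' little-endian, channel-major as stored), `meta.json` (schema version,
#' array dimensions, sample rate, channel table, session metadata) and
#' `events.csv` (onsets in seconds, 0-based within the trial window, full
#' double precision). The round trip through [read_session()] is lossless.
#'
#' @param session a [recording_session()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "traces.bin"), "wb")
  writeBin(as.numeric(session$traces), con, size = 8, endian = "little")
  close(con)
  meta <- list(schema_version = 1L,
               dim = dim(session$traces),
               sample_rate = session$sample_rate,
               channels = session$channels,
               metadata = session$metadata)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(session$events, file.path(path, "events.csv"))
  invisible(path)
}

#' Read a recording session from disk
#'
#' Inverse of [write_session()]. The trace file's size is checked against
#' the sidecar dimensions, so truncation or corruption errors out rather
#' than yielding a silently short array.
#'
#' @param path directory written by [write_session()].
#' @return a [recording_session()].
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  bin_path <- file.path(path, "traces.bin")
  ev_path <- file.path(path, "events.csv")
  if (!all(file.exists(meta_path, bin_path, ev_path)))
    stop("not a session directory (missing meta.json/traces.bin/events.csv): ",
         path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L)
    stop("unsupported session schema version: ",
         meta$schema_version %||% "<missing>", call. = FALSE)
  dims <- as.integer(meta$dim)
  n <- prod(dims)
  if (file.info(bin_path)$size != n * 8)
    stop("traces.bin size (", file.info(bin_path)$size,
         " bytes) does not match sidecar dimensions (expected ", n * 8,
         "): corrupted container", call. = FALSE)
  con <- file(bin_path, "rb")
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  events <- readr::read_csv(ev_path, show_col_types = FALSE)
  md <- meta$metadata
  if (!is.null(md$day)) md$day <- as.integer(md$day)
  recording_session(array(x, dim = dims), meta$sample_rate,
                    tibble::as_tibble(meta$channels), events, metadata = md)
}
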