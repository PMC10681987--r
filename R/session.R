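#' Trial-aligned recording session
#'
#' A `recording_session` bundles trial-aligned multi-channel voltage traces
#' with their channel metadata, event table and session metadata. It is the
#' common input of [compute_arm()] and [compute_earm()] and the output of the
#' synthetic generators [generate_session()] and [generate_erp_session()].
#'
#' @param traces numeric array `[n_channels, n_trials, n_samples]`, volts.
#' @param sample_rate sampling rate in Hz.
#' @param channels tibble with one row per channel: `channel` (id),
#'   `hemisphere` (`"L"`/`"R"`), and either `position`
#'   (`"caudal"`/`"rostral"`) or `depth` (micrometres), or both.
#' @param events tibble with one row per stimulus presentation: `trial`
#'   (1-based trial index), `stimulus` (id), `onset` (seconds within the
#'   trial window), `duration` (seconds), `presentation` (1-based index of
#'   this stimulus' repetitions).
#' @param metadata named list; recognised fields are `subject`, `day`
#'   (relative to exposure onset, baseline days negative), `condition`,
#'   `modality` (`"MUA"` or `"ERP"`).
#'
#' @details Every event must satisfy the analysis-window invariant: the
#' interval `[onset - 0.5 s, onset + duration + 0.1 s]` lies within the
#' recorded trial window, so that both the 500 ms pre-stimulus control window
#' and the stimulus-plus-100-ms response window are fully sampled.
#' Presentation indices are checked to be contiguous from 1 per stimulus.
#'
#' @return an object of class `recording_session`.
#' @export
recording_session <- function(traces, sample_rate, channels, events,
                              metadata = list()) {
  stopifnot(is.array(traces), length(dim(traces)) == 3)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number", call. = FALSE)
  channels <- tibble::as_tibble(channels)
  events <- tibble::as_tibble(events)
  req_ch <- c("channel", "hemisphere")
  if (!all(req_ch %in% names(channels)))
    stop("channels needs columns: ", paste(req_ch, collapse = ", "), call. = FALSE)
  if (!all(channels$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  req_ev <- c("trial", "stimulus", "onset", "duration", "presentation")
  if (!all(req_ev %in% names(events)))
    stop("events needs columns: ", paste(req_ev, collapse = ", "), call. = FALSE)
  if (nrow(channels) != dim(traces)[1])
    stop("channels rows must match dim(traces)[1]", call. = FALSE)

  x <- structure(
    list(traces = traces, sample_rate = sample_rate, channels = channels,
         events = events, metadata = metadata),
    class = "recording_session")
  validate_session(x)
  x
}

#' Validate a recording session
#'
#' Checks the window invariant (baseline and response windows inside the
#' trial window) and presentation-index contiguity. Called by
#' [recording_session()]; exported for use after manual edits.
#'
#' @param x a `recording_session`.
#' @param baseline_s,post_s analysis-window margins (seconds before onset and
#'   after stimulus offset) that must fit inside the trial window.
#' @return `x`, invisibly; errors describe the offending events.
#' @export
validate_session <- function(x, baseline_s = 0.5, post_s = 0.1) {
  stopifnot(inherits(x, "recording_session"))
  trial_len <- dim(x$traces)[3] / x$sample_rate
  ev <- x$events
  bad <- ev$onset - baseline_s < 0 |
    ev$onset + ev$duration + post_s > trial_len + 1e-12
  if (any(bad))
    stop("events violate the analysis-window invariant (need [onset-",
         baseline_s, ", onset+duration+", post_s, "] within the ",
         signif(trial_len, 6), " s trial window): rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  if (any(ev$trial < 1 | ev$trial > dim(x$traces)[2]))
    stop("event trial indices outside the recorded trials", call. = FALSE)
  cont <- ev |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::summarise(ok = setequal(.data$presentation,
                                   seq_len(max(.data$presentation))),
                     .groups = "drop")
  if (!all(cont$ok))
    stop("presentation indices are not contiguous from 1 for stimulus: ",
         paste(cont$stimulus[!cont$ok], collapse = ", "), call. = FALSE)
  invisible(x)
}

#' @export
print.recording_session <- function(x, ...) {
  d <- dim(x$traces)
  md <- x$metadata
  cat("<recording_session> ", d[1], " channels x ", d[2], " trials x ",
      d[3], " samples @ ", x$sample_rate, " Hz\n", sep = "")
  cat("  events: ", nrow(x$events), " presentations of ",
      dplyr::n_distinct(x$events$stimulus), " stimuli\n", sep = "")
  if (length(md))
    cat("  ", paste(names(md), unlist(md), sep = "=", collapse = "  "),
        "\n", sep = "")
  invisible(x)
}

# metadata columns prepended to per-channel result tables
session_id_cols <- function(x) {
  md <- x$metadata
  tibble::tibble(
    subject = md$subject %||% NA_character_,
    day = md$day %||% NA_integer_,
    condition = md$condition %||% NA_character_)
}
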