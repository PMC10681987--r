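#' Windowed root-mean-square of a voltage trace
#'
#' RMS over the half-open time window `[start, end)`, discretized to sample
#' indices `[floor(start*fs), floor(end*fs))` so that adjoining windows (the
#' pre-stimulus baseline and the stimulus-on window meeting at onset) never
#' share a sample.
#'
#' @param trace numeric vector of voltage samples.
#' @param window numeric length-2, window start and end in seconds.
#' @param sample_rate sampling rate in Hz.
#' @return RMS amplitude in volts (a single number).
#' @examples
#' windowed_rms(rep(2, 100), c(0, 0.1), 1000)  # 2
#' @export
windowed_rms <- function(trace, window, sample_rate) {
  stopifnot(is.numeric(trace), length(window) == 2)
  idx <- window_indices(window[1], window[2], sample_rate, length(trace))
  rms(trace[idx])
}

#' Per-trial absolute response magnitudes (ARM)
#'
#' For every (channel, stimulus presentation) the RMS of the 500 ms
#' pre-stimulus control window is subtracted from the RMS of the stimulus-on
#' window (stimulus duration plus 100 ms):
#' `arm = rms([onset, onset+dur+0.1)) - rms([onset-0.5, onset))`.
#'
#' Intended for multi-unit activity (MUA) sessions; it runs on ERP traces
#' too, which is occasionally useful for diagnostics. RMS is computed on the
#' stored trace as-is — no rectification or re-filtering (recordings are
#' assumed band-passed at acquisition).
#'
#' @param session a [recording_session()].
#' @param baseline_s control-window length before onset, seconds (default
#'   0.5).
#' @param post_s response-window extension past stimulus offset, seconds
#'   (default 0.1).
#' @return tibble with one row per (channel, stimulus, presentation):
#'   session id columns (`subject`, `day`, `condition`), `channel`,
#'   `hemisphere`, `position` and/or `depth` when present, `stimulus`,
#'   `presentation`, `rms_stim`, `rms_base`, `arm` (volts).
#' @export
compute_arm <- function(session, baseline_s = 0.5, post_s = 0.1) {
  stopifnot(inherits(session, "recording_session"))
  validate_session(session, baseline_s = baseline_s, post_s = post_s)
  fs <- session$sample_rate
  n_samp <- dim(session$traces)[3]
  ev <- session$events
  ch <- session$channels

  per_event <- purrr::map(seq_len(nrow(ev)), function(i) {
    on <- ev$onset[i]
    idx_stim <- window_indices(on, on + ev$duration[i] + post_s, fs, n_samp)
    idx_base <- window_indices(on - baseline_s, on, fs, n_samp)
    seg <- session$traces[, ev$trial[i], , drop = FALSE]
    dim(seg) <- dim(seg)[c(1, 3)]
    rs <- sqrt(rowMeans(seg[, idx_stim, drop = FALSE]^2))
    rb <- sqrt(rowMeans(seg[, idx_base, drop = FALSE]^2))
    tibble::tibble(channel = ch$channel, stimulus = ev$stimulus[i],
                   presentation = ev$presentation[i],
                   rms_stim = rs, rms_base = rb, arm = rs - rb)
  })
  out <- dplyr::bind_rows(per_event)
  out <- dplyr::left_join(out, ch, by = "channel")
  meta_cols <- intersect(c("hemisphere", "position", "depth"), names(out))
  dplyr::bind_cols(session_id_cols(session)[rep(1, nrow(out)), ], out) |>
    dplyr::select(dplyr::all_of(c("subject", "day", "condition", "channel",
                                  meta_cols, "stimulus", "presentation",
                                  "rms_stim", "rms_base", "arm")))
}

#' Mean ARM over early presentations (trials 2-6)
#'
#' Averages per-trial ARMs over presentation indices 2-6 of each stimulus,
#' the window used to quantify response strength before adaptation has run
#' its course (trial 1, the strongest novelty response, is excluded).
#' Groups missing any of the requested presentations are emitted with
#' `complete = FALSE`, never silently dropped.
#'
#' @param responses tibble from [compute_arm()].
#' @param trials integer vector of presentation indices to average (default
#'   `2:6`).
#' @return tibble with one row per (channel, stimulus) group: grouping and
#'   metadata columns, `n_trials` found, `complete`, `mean_arm`.
#' @export
mean_arm_early <- function(responses, trials = 2:6) {
  stopifnot(all(c("channel", "stimulus", "presentation", "arm") %in%
                  names(responses)))
  grp <- intersect(c("subject", "day", "condition", "channel", "hemisphere",
                     "position", "depth", "stimulus"), names(responses))
  responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_trials = sum(.data$presentation %in% trials),
      complete = .data$n_trials == length(trials),
      mean_arm = ifelse(.data$n_trials > 0,
                        mean(.data$arm[.data$presentation %in% trials]),
                        NA_real_),
      .groups = "drop")
}

#' Trial-averaged ERP response magnitudes (eARM)
#'
#' For each (channel, stimulus) the waveforms of the first
#' `min(max_trials, available)` presentations are averaged sample-wise, and
#' the ARM window arithmetic is then applied to the averaged waveform:
#' `earm = rms(stimulus window) - rms(baseline window)`. Averaging first
#' (rather than averaging per-trial ARMs) is what stabilizes the ERP before
#' any RMS is taken; on noisy data the two orders differ.
#'
#' @param session an ERP [recording_session()]. All presentations of a
#'   stimulus must share onset and duration (trial-aligned).
#' @param max_trials number of initial presentations to average (default 25).
#' @inheritParams compute_arm
#' @return tibble with one row per (channel, stimulus): id columns,
#'   `n_trials_averaged`, `rms_stim`, `rms_base`, `earm` (volts).
#' @export
compute_earm <- function(session, max_trials = 25, baseline_s = 0.5,
                         post_s = 0.1) {
  stopifnot(inherits(session, "recording_session"))
  validate_session(session, baseline_s = baseline_s, post_s = post_s)
  fs <- session$sample_rate
  n_samp <- dim(session$traces)[3]
  ch <- session$channels

  per_stim <- session$events |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::group_split() |>
    purrr::map(function(ev) {
      if (dplyr::n_distinct(ev$onset) > 1 || dplyr::n_distinct(ev$duration) > 1)
        stop("stimulus ", ev$stimulus[1],
             ": presentations differ in onset/duration; cannot average",
             call. = FALSE)
      ev <- dplyr::arrange(ev, .data$presentation)
      use <- utils::head(ev$trial, max_trials)
      avg <- apply(session$traces[, use, , drop = FALSE], c(1, 3), mean)
      on <- ev$onset[1]
      idx_stim <- window_indices(on, on + ev$duration[1] + post_s, fs, n_samp)
      idx_base <- window_indices(on - baseline_s, on, fs, n_samp)
      rs <- sqrt(rowMeans(avg[, idx_stim, drop = FALSE]^2))
      rb <- sqrt(rowMeans(avg[, idx_base, drop = FALSE]^2))
      tibble::tibble(channel = ch$channel, stimulus = ev$stimulus[1],
                     n_trials_averaged = length(use),
                     rms_stim = rs, rms_base = rb, earm = rs - rb)
    })
  out <- dplyr::bind_rows(per_stim)
  out <- dplyr::left_join(out, ch, by = "channel")
  meta_cols <- intersect(c("hemisphere", "position", "depth"), names(out))
  dplyr::bind_cols(session_id_cols(session)[rep(1, nrow(out)), ], out) |>
    dplyr::select(dplyr::all_of(c("subject", "day", "condition", "channel",
                                  meta_cols, "stimulus", "n_trials_averaged",
                                  "rms_stim", "rms_base", "earm")))
}
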