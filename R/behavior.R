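#' Score a Go/NoGo log into 50-trial blocks
#'
#' Partitions each subject's trials, in chronological order, into
#' consecutive non-overlapping blocks of `block_size` trials. Blocks are
#' defined purely by trial count and may span day boundaries. A final
#' partial block is emitted with `complete = FALSE` and is excluded from
#' criterion logic.
#'
#' @param log behavior-log tibble with columns `subject`, `day`, `trial`,
#'   `correct` (e.g. from [generate_behavior_log()]).
#' @param block_size trials per block (default 50).
#' @return tibble: `subject`, `block` (1-based), `day_first`, `day_last`,
#'   `n_trials`, `complete`, `p_correct`.
#' @export
score_blocks <- function(log, block_size = 50) {
  stopifnot(all(c("subject", "day", "trial", "correct") %in% names(log)))
  dup <- log |>
    dplyr::count(.data$subject, .data$day, .data$trial) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    stop("duplicated (subject, day, trial): e.g. ", dup$subject[1], " day ",
         dup$day[1], " trial ", dup$trial[1], call. = FALSE)
  log |>
    dplyr::arrange(.data$subject, .data$day, .data$trial) |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(block = (dplyr::row_number() - 1L) %/% block_size + 1L) |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::summarise(day_first = min(.data$day), day_last = max(.data$day),
                     n_trials = dplyr::n(),
                     complete = .data$n_trials == block_size,
                     p_correct = mean(.data$correct), .groups = "drop")
}

#' Detect attainment of the discrimination criterion
#'
#' A subject reaches criterion at the first pair of consecutive complete
#' blocks whose proportions correct are both `>= threshold` ("reached or
#' exceeded 80%" with the defaults). `day_reached` is the calendar day
#' containing the second block's last trial, and `final_performance` is the
#' proportion correct over all of that day's trials; subjects that never
#' reach criterion within `max_days` report the final training day's
#' performance with `reached = FALSE`.
#'
#' @inheritParams score_blocks
#' @param threshold block proportion correct required (default 0.8).
#' @param consecutive number of consecutive qualifying blocks (default 2).
#' @param max_days training horizon in days; trials beyond it are ignored
#'   (default 21).
#' @return tibble, one row per subject: `subject`, `reached`,
#'   `day_reached` (`NA` if not reached), `block_reached` (index of the last
#'   block of the qualifying run), `days_to_criterion`, `final_performance`.
#' @export
detect_criterion <- function(log, threshold = 0.8, consecutive = 2,
                             block_size = 50, max_days = 21) {
  log <- dplyr::filter(log, .data$day <= max_days)
  blocks <- score_blocks(log, block_size = block_size)
  log |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_split() |>
    purrr::map(function(sl) {
      subj <- sl$subject[1]
      bl <- dplyr::filter(blocks, .data$subject == subj, .data$complete)
      qual <- bl$p_correct >= threshold
      run_end <- NA_integer_
      if (length(qual) >= consecutive) {
        ends <- which(vapply(seq_len(length(qual) - consecutive + 1),
                             function(i) all(qual[i:(i + consecutive - 1)]),
                             logical(1)))
        if (length(ends) > 0) run_end <- ends[1] + consecutive - 1L
      }
      reached <- !is.na(run_end)
      perf_day <- if (reached) bl$day_last[run_end] else max(sl$day)
      day_trials <- dplyr::filter(sl, .data$day == perf_day)
      tibble::tibble(
        subject = subj, reached = reached,
        day_reached = if (reached) perf_day else NA_integer_,
        block_reached = if (reached) bl$block[run_end] else NA_integer_,
        days_to_criterion = if (reached) perf_day else NA_integer_,
        final_performance = mean(day_trials$correct))
    }) |>
    dplyr::bind_rows()
}

#' Group-level behavioral summary
#'
#' Tallies criterion attainment per (condition, exposure-duration) group:
#' how many subjects reached criterion, mean days-to-criterion among the
#' reachers, and mean final performance over all subjects.
#'
#' @param results per-subject tibble from [detect_criterion()].
#' @param groups tibble assigning each `subject` to a group (columns
#'   `subject` plus grouping columns, e.g. `condition`, `exposure_days`).
#' @return tibble, one row per group: grouping columns, `n_total`,
#'   `n_reached`, `prop_reached`, `mean_days_to_criterion` (reachers only,
#'   `NaN` if none), `mean_final_performance`.
#' @export
summarize_groups <- function(results, groups) {
  stopifnot("subject" %in% names(groups))
  grp_cols <- setdiff(names(groups), "subject")
  joined <- dplyr::inner_join(results, groups, by = "subject")
  missing <- setdiff(results$subject, groups$subject)
  if (length(missing) > 0)
    warning("subjects without a group assignment omitted: ",
            paste(missing, collapse = ", "), call. = FALSE)
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_reached = sum(.data$reached),
      prop_reached = mean(.data$reached),
      mean_days_to_criterion = mean(.data$days_to_criterion[.data$reached]),
      mean_final_performance = mean(.data$final_performance),
      .groups = "drop")
}
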