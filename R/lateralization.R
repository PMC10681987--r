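#' Hemisphere-averaged response magnitudes
#'
#' Averages per-channel response magnitudes into one value per hemisphere
#' per session. Per-stimulus values are first averaged within channel (equal
#' stimulus weighting regardless of trial counts), then channel means are
#' averaged within hemisphere. With `channels = "caudal_only"` rostral
#' channels are dropped before averaging — useful for epidural montages
#' where only the caudal pins overlie the auditory lobule.
#'
#' @param values tibble of per-channel magnitudes, e.g. from
#'   [compute_earm()] (column `earm`) or [mean_arm_early()] (column
#'   `mean_arm`); must contain `channel`, `hemisphere` and the value column.
#' @param value value column name (default `"earm"`).
#' @param channels `"all"` (default) or `"caudal_only"` (requires a
#'   `position` column).
#' @return tibble with one row per session (grouped by whichever of
#'   `subject`, `day`, `condition` are present): grouping columns plus `R`
#'   and `L` (volts).
#' @export
hemisphere_average <- function(values, value = "earm",
                               channels = c("all", "caudal_only")) {
  channels <- match.arg(channels)
  stopifnot(value %in% names(values),
            all(c("channel", "hemisphere") %in% names(values)))
  if (channels == "caudal_only") {
    if (!"position" %in% names(values))
      stop("channels = 'caudal_only' needs a position column", call. = FALSE)
    values <- dplyr::filter(values, .data$position == "caudal")
  }
  sess <- intersect(c("subject", "day", "condition"), names(values))
  per_channel <- values |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(sess, "hemisphere",
                                                  "channel")))) |>
    dplyr::summarise(m = mean(.data[[value]]), .groups = "drop")
  wide <- per_channel |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(sess, "hemisphere")))) |>
    dplyr::summarise(m = mean(.data$m), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "hemisphere", values_from = "m")
  if (!all(c("L", "R") %in% names(wide)) || anyNA(wide$L) || anyNA(wide$R))
    stop("a session is missing channels in one hemisphere; LI undefined",
         call. = FALSE)
  dplyr::select(wide, dplyr::all_of(c(sess, "R", "L")))
}

#' Lateralization index
#'
#' `LI = (R - L) / ((R + L) / 2)`: the signed difference between the
#' hemisphere-averaged response magnitudes divided by their arithmetic mean.
#' Positive values indicate right-biased responses, negative left-biased;
#' for non-negative magnitudes LI lies in `[-2, 2]`.
#'
#' @param R,L hemisphere-averaged response magnitudes (vectorized).
#' @return unitless LI; `NA` where `R + L = 0` (undefined).
#' @examples
#' lateralization_index(3, 1)  # 1
#' lateralization_index(0, 5)  # -2
#' @export
lateralization_index <- function(R, L) {
  li <- (R - L) / ((R + L) / 2)
  li[(R + L) == 0] <- NA_real_
  li
}

#' Per-session lateralization records
#'
#' Convenience composition: [hemisphere_average()] then
#' [lateralization_index()], giving one `li_raw` per session.
#'
#' @inheritParams hemisphere_average
#' @return tibble: session columns, `R`, `L`, `li_raw`.
#' @export
li_records <- function(values, value = "earm", channels = "all") {
  hemisphere_average(values, value = value, channels = channels) |>
    dplyr::mutate(li_raw = lateralization_index(.data$R, .data$L))
}

#' Baseline-correct lateralization indices
#'
#' Subtracts, per subject, the mean of that subject's baseline-period LIs
#' (sessions with `day < 0`) from every LI, so each bird's exposure
#' trajectory is referenced to its own pre-exposure bias. Baseline sessions
#' also carry `li_corrected` (their per-subject mean is 0 by construction).
#'
#' @param records tibble with columns `subject`, `day`, `li_raw`.
#' @return `records` with `li_corrected` added.
#' @export
baseline_correct <- function(records) {
  stopifnot(all(c("subject", "day", "li_raw") %in% names(records)))
  has_base <- records |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(ok = any(.data$day < 0), .groups = "drop")
  if (!all(has_base$ok))
    stop("no baseline (day < 0) session for subject: ",
         paste(has_base$subject[!has_base$ok], collapse = ", "),
         call. = FALSE)
  records |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(li_corrected = .data$li_raw -
                    mean(.data$li_raw[.data$day < 0])) |>
    dplyr::ungroup()
}

#' Assign exposure days to 3-day bins
#'
#' Exposure days (day >= 0) are binned as
#' `[bin_width*floor(day/bin_width), bin_width*floor(day/bin_width) + bin_width - 1]`,
#' labelled `"0-2"`, `"3-5"`, ..., `"18-20"` for a 21-day exposure with the
#' default width. Baseline days (day < 0) get the label `"baseline"`.
#'
#' @param records tibble with a `day` column.
#' @param bin_width days per bin (default 3).
#' @return `records` with an ordered-factor `bin_label` column added.
#' @export
bin_days <- function(records, bin_width = 3) {
  stopifnot("day" %in% names(records))
  lo <- bin_width * floor(records$day / bin_width)
  lab <- ifelse(records$day < 0, "baseline",
                paste0(lo, "-", lo + bin_width - 1))
  lv <- unique(lab[order(records$day)])
  lv <- c("baseline"[("baseline" %in% lv)], setdiff(lv, "baseline"))
  dplyr::mutate(records, bin_label = factor(lab, levels = lv, ordered = TRUE))
}

#' MUA lateralization summary
#'
#' Builds per-session lateralization records from MUA data: per-channel mean
#' ARMs (trials 2-6, from [mean_arm_early()]) restricted to sites kept by
#' the adaptation filter, hemisphere-averaged, converted to LI.
#'
#' @param arm_means tibble from [mean_arm_early()].
#' @param kept_sites optional tibble of sites from [filter_sites()] (`kept`
#'   column); if supplied only kept channels contribute.
#' @param channels passed to [hemisphere_average()].
#' @return tibble: session columns, `R`, `L`, `li_raw`.
#' @export
mua_li_summary <- function(arm_means, kept_sites = NULL, channels = "all") {
  if (!is.null(kept_sites)) {
    keep_cols <- intersect(c("subject", "day", "condition", "channel"),
                           intersect(names(arm_means), names(kept_sites)))
    kept <- dplyr::filter(kept_sites, .data$kept)
    arm_means <- dplyr::semi_join(arm_means, kept, by = keep_cols)
  }
  li_records(arm_means, value = "mean_arm", channels = channels)
}
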