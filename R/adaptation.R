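#' Normalized stimulus-specific adaptation rates (AdR)
#'
#' For each (channel, stimulus), the adaptation rate is the ordinary
#' least-squares slope of per-trial ARM against presentation index over
#' trials 6-25, divided by the mean ARM of those trials:
#' `adr = slope / mean_arm_6_25`. Normalizing by the mean removes
#' between-site differences in absolute response strength, so `adr` is the
#' fractional drop in response per repetition. Strongly negative values are
#' the stimulus-specific-adaptation signature of NCM sites; values near zero
#' indicate non-adapting (or already familiar) responses.
#'
#' Groups missing any presentation in `trials` are emitted with
#' `defined = FALSE` and are never imputed. A non-positive mean ARM also
#' leaves `adr` undefined (non-responsive site).
#'
#' @param responses tibble from [compute_arm()].
#' @param trials presentation indices of the regression window (default
#'   `6:25`).
#' @param criterion inclusion threshold: a result is `included` iff
#'   `adr < criterion` strictly (default -0.05).
#' @return tibble with one row per (channel, stimulus): id columns, `slope`
#'   (volts/presentation), `mean_arm` over the window, `adr`
#'   (dimensionless), `defined`, `included`.
#' @export
compute_adr <- function(responses, trials = 6:25, criterion = -0.05) {
  stopifnot(all(c("channel", "stimulus", "presentation", "arm") %in%
                  names(responses)))
  grp <- intersect(c("subject", "day", "condition", "channel", "hemisphere",
                     "position", "depth", "stimulus"), names(responses))
  responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_trials = sum(.data$presentation %in% trials),
      slope = if (.data$n_trials == length(trials)) {
        x <- .data$presentation[.data$presentation %in% trials]
        y <- .data$arm[.data$presentation %in% trials]
        sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      } else NA_real_,
      mean_arm = if (.data$n_trials == length(trials))
        mean(.data$arm[.data$presentation %in% trials]) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      defined = .data$n_trials == length(trials) & !is.na(.data$mean_arm) &
        .data$mean_arm > 0,
      adr = ifelse(.data$defined, .data$slope / .data$mean_arm, NA_real_),
      included = !is.na(.data$adr) & .data$adr < criterion)
}

#' Site-level adaptation filter
#'
#' Aggregates per-stimulus AdRs to one value per recording site (channel)
#' and keeps a site iff its aggregated AdR is strictly below `criterion`.
#' This is the NCM inclusion filter: sites without the characteristic
#' adaptation profile (e.g. Field-L-like sites) are excluded from further
#' analysis. The exclusion fraction is reported for audit against the
#' expected 10-12% regime.
#'
#' @param results tibble from [compute_adr()].
#' @param site_rule how to aggregate defined per-stimulus AdRs within a
#'   site: `"mean"` (default), `"median"`, or `"any"` (keep if any stimulus
#'   meets the criterion).
#' @param criterion strict threshold (default -0.05).
#' @return list with `sites` (tibble: id columns, `site_adr`, `n_defined`,
#'   `kept`, `reason`) and `exclusion_fraction`.
#' @export
filter_sites <- function(results, site_rule = c("mean", "median", "any"),
                         criterion = -0.05) {
  site_rule <- match.arg(site_rule)
  grp <- intersect(c("subject", "day", "condition", "channel", "hemisphere",
                     "position", "depth"), names(results))
  sites <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_defined = sum(.data$defined),
      site_adr = switch(site_rule,
        mean = mean(.data$adr[.data$defined]),
        median = stats::median(.data$adr[.data$defined]),
        any = if (any(.data$defined)) min(.data$adr[.data$defined]) else NaN),
      .groups = "drop") |>
    dplyr::mutate(
      kept = .data$n_defined > 0 & !is.na(.data$site_adr) &
        .data$site_adr < criterion,
      reason = dplyr::case_when(
        .data$n_defined == 0 ~ "no_defined_adr",
        !.data$kept ~ "adaptation_criterion",
        TRUE ~ NA_character_))
  list(sites = sites,
       exclusion_fraction = mean(!sites$kept))
}
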