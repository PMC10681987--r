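#' End-to-end pipeline configuration
#'
#' Assembles every stage parameter with the analysis constants at their
#' standard values: 0.5 s baseline window, +100 ms response-window offset,
#' ARM averaging trials 2-6, AdR regression trials 6-25, inclusion criterion
#' AdR < -0.05, 3-day bins, 80% criterion on 2 consecutive 50-trial blocks,
#' 21-day training horizon. Simulation sizes default to a desk-scale cohort
#' (two conditions x 4 subjects, one ERP session per 3-day bin, 25
#' presentations per stimulus at 2 kHz) so a full run completes in seconds;
#' any [sim_config()] field can be overridden through `sim`.
#'
#' @param seed master seed; all per-session streams derive from it.
#' @param out_dir output directory for tables and the run manifest.
#' @param conditions profile conditions to simulate.
#' @param n_subjects subjects per condition.
#' @param baseline_days,exposure_days session days per subject (baseline
#'   days negative).
#' @param sim named list of [sim_config()] overrides.
#' @param g_high hemispheric gain of the biased phases (see
#'   [lateralization_profile()]).
#' @param channel_selection `"all"` or `"caudal_only"` for the LI stage.
#' @param bin_width days per time bin.
#' @param behavior named list: `n_days`, `n_trials_per_day`, plus per-group
#'   learning parameters `fast` / `slow` (lists with `asymptote`,
#'   `learning_rate`); Het-Env cohorts use `fast`, others `slow`.
#' @param criterion_threshold,criterion_blocks,block_size,max_days Go/NoGo
#'   criterion parameters.
#' @param stages character subset of
#'   `c("lateralization", "behavior", "stats")`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("neurolat_run_"),
                            conditions = c("Con-Env", "Het-Env"),
                            n_subjects = 4L,
                            baseline_days = c(-4L, -2L),
                            exposure_days = seq(1L, 19L, by = 3L),
                            sim = list(sample_rate = 2000,
                                       erp_n_presentations = 25L),
                            g_high = 1.5,
                            channel_selection = "all",
                            bin_width = 3,
                            behavior = list(
                              n_days = 21L, n_trials_per_day = 100L,
                              fast = list(asymptote = 0.95,
                                          learning_rate = 0.12),
                              slow = list(asymptote = 0.55,
                                          learning_rate = 0.1)),
                            criterion_threshold = 0.8,
                            criterion_blocks = 2,
                            block_size = 50,
                            max_days = 21,
                            stages = c("lateralization", "behavior",
                                       "stats")) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 conditions = conditions, n_subjects = as.integer(n_subjects),
                 baseline_days = as.integer(baseline_days),
                 exposure_days = as.integer(exposure_days),
                 sim = sim, g_high = g_high,
                 channel_selection = channel_selection,
                 bin_width = bin_width, behavior = behavior,
                 criterion_threshold = criterion_threshold,
                 criterion_blocks = criterion_blocks,
                 block_size = block_size, max_days = max_days,
                 stages = stages),
            class = "pipeline_config")
}

stage_log <- function(stage, ..., quiet = FALSE) {
  if (!quiet)
    message("[", stage, "] ",
            paste(names(c(...)), c(...), sep = "=", collapse = " "))
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes simulate -> response metrics -> lateralization -> behavior ->
#' stats as configured, writes the output tables (`earm.csv`, `li.csv`,
#' `behavior_log.csv`, `behavior_performance.csv`, `behavior_groups.csv`,
#' `stats_anova.csv`, `stats_posthoc.csv`) plus a `manifest.json` carrying
#' the package version, master seed and full parameter set (with a
#' deterministic hash), sufficient to re-run bit-identically via
#' [run_pipeline_from_manifest()].
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return a `lat_pipeline` list: `li`, `earm`, `behavior`,
#'   `behavior_groups`, `anova`, `posthoc`, `manifest_path`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  days <- c(config$baseline_days, config$exposure_days)

  earm_all <- li <- behavior_log <- behavior_perf <- behavior_groups <- NULL
  anova_res <- posthoc_res <- NULL

  if ("lateralization" %in% config$stages) {
    sessions <- list()
    earm_all <- purrr::imap(config$conditions, function(cond, ci) {
      profile <- lateralization_profile(cond, g_high = config$g_high)
      purrr::map(seq_len(config$n_subjects), function(si) {
        subj <- paste0(tolower(substr(gsub("-", "", cond), 1, 3)), si)
        subject_index <- (ci - 1L) * config$n_subjects + si
        purrr::map(days, function(d) {
          sim <- do.call(sim_config, c(list(seed = config$seed), config$sim))
          sess <- generate_erp_session(sim, profile, d, subject = subj,
                                       subject_index = subject_index)
          compute_earm(sess)
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    stage_log("metrics", c(sessions = length(config$conditions) *
                             config$n_subjects * length(days),
                           earm_rows = nrow(earm_all)), quiet = quiet)

    li <- earm_all |>
      li_records(value = "earm", channels = config$channel_selection) |>
      baseline_correct() |>
      bin_days(bin_width = config$bin_width)
    stage_log("lateralization", c(rows = nrow(li)), quiet = quiet)
    readr::write_csv(earm_all, file.path(config$out_dir, "earm.csv"))
    readr::write_csv(li, file.path(config$out_dir, "li.csv"))
  }

  if ("behavior" %in% config$stages) {
    bcfg <- config$behavior
    groups <- tidyr::expand_grid(condition = config$conditions,
                                 si = seq_len(config$n_subjects))
    behavior_log <- purrr::pmap(groups, function(condition, si) {
      pars <- if (condition == "Het-Env") bcfg$fast else bcfg$slow
      gcfg <- behavior_sim_config(
        seed = config$seed * 131L + match(condition, config$conditions) *
          1000L + si,
        asymptote = pars$asymptote, learning_rate = pars$learning_rate,
        n_trials_per_day = bcfg$n_trials_per_day)
      generate_behavior_log(gcfg, n_days = bcfg$n_days,
                            subject = paste0("b_", condition, "_", si))
    }) |> dplyr::bind_rows()
    behavior_perf <- detect_criterion(
      behavior_log, threshold = config$criterion_threshold,
      consecutive = config$criterion_blocks, block_size = config$block_size,
      max_days = config$max_days)
    assign <- groups |>
      dplyr::mutate(subject = paste0("b_", .data$condition, "_", .data$si)) |>
      dplyr::select("subject", "condition")
    behavior_groups <- summarize_groups(behavior_perf, assign)
    stage_log("behavior", c(trials = nrow(behavior_log),
                            reached = sum(behavior_perf$reached)),
              quiet = quiet)
    readr::write_csv(behavior_log,
                     file.path(config$out_dir, "behavior_log.csv"))
    readr::write_csv(behavior_perf,
                     file.path(config$out_dir, "behavior_performance.csv"))
    readr::write_csv(behavior_groups,
                     file.path(config$out_dir, "behavior_groups.csv"))
  }

  if ("stats" %in% config$stages && !is.null(li)) {
    exposure <- dplyr::filter(li, .data$day >= 0) |>
      dplyr::mutate(bin_label = as.character(.data$bin_label))
    anova_res <- factorial_anova(exposure, "li_corrected",
                                 c("condition", "bin_label"))
    posthoc_res <- posthoc_pairwise(exposure, "li_corrected", "condition",
                                    by = "bin_label")
    stage_log("stats", c(effects = nrow(tidy(anova_res)),
                         comparisons = nrow(posthoc_res)), quiet = quiet)
    readr::write_csv(tidy(anova_res),
                     file.path(config$out_dir, "stats_anova.csv"))
    readr::write_csv(posthoc_res,
                     file.path(config$out_dir, "stats_posthoc.csv"))
  }

  params <- unclass(config)
  params_json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "neurolat",
                   version = as.character(utils::packageVersion("neurolat")),
                   seed = config$seed,
                   param_hash = param_hash(as.character(params_json)),
                   params = params)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  structure(list(li = li, earm = earm_all, behavior = behavior_perf,
                 behavior_log = behavior_log,
                 behavior_groups = behavior_groups, anova = anova_res,
                 posthoc = posthoc_res, manifest_path = manifest_path,
                 out_dir = config$out_dir),
            class = "lat_pipeline")
}

#' Re-run a pipeline from its manifest
#'
#' Reads a `manifest.json` written by [run_pipeline()] and re-executes the
#' pipeline with the recorded parameters and seed. With the same `out_dir`,
#' outputs are byte-identical to the original run.
#'
#' @param manifest_path path to a manifest file.
#' @param out_dir optional override of the output directory.
#' @param quiet suppress stage logs.
#' @return a `lat_pipeline` (see [run_pipeline()]).
#' @export
run_pipeline_from_manifest <- function(manifest_path, out_dir = NULL,
                                       quiet = TRUE) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  p <- manifest$params
  cfg <- pipeline_config(
    seed = p$seed, out_dir = out_dir %||% p$out_dir,
    conditions = p$conditions, n_subjects = p$n_subjects,
    baseline_days = p$baseline_days, exposure_days = p$exposure_days,
    sim = as.list(p$sim), g_high = p$g_high,
    channel_selection = p$channel_selection, bin_width = p$bin_width,
    behavior = lapply(p$behavior, function(x)
      if (is.list(x)) as.list(x) else x),
    criterion_threshold = p$criterion_threshold,
    criterion_blocks = p$criterion_blocks, block_size = p$block_size,
    max_days = p$max_days, stages = p$stages)
  run_pipeline(cfg, quiet = quiet)
}

#' @export
print.lat_pipeline <- function(x, ...) {
  cat("<lat_pipeline> outputs in ", x$out_dir, "\n", sep = "")
  if (!is.null(x$li))
    cat("  li: ", nrow(x$li), " session records, ",
        dplyr::n_distinct(x$li$subject), " subjects\n", sep = "")
  if (!is.null(x$behavior))
    cat("  behavior: ", nrow(x$behavior), " subjects, ",
        sum(x$behavior$reached), " reached criterion\n", sep = "")
  invisible(x)
}
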