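prof_sil <- lateralization_profile("Silence")

test_that("generated sessions are reproducible bit-for-bit", {
  cfg <- sim_config(seed = 42, sample_rate = 500, n_stimuli = 2,
                    n_presentations = 5, stimulus_duration = 0.3,
                    n_channels_per_hemisphere = 1)
  s1 <- generate_session(cfg, prof_sil, 2)
  s2 <- generate_session(cfg, prof_sil, 2)
  expect_identical(s1, s2)
  # different day -> different stream
  s3 <- generate_session(cfg, prof_sil, 3)
  expect_false(identical(s1$traces, s3$traces))
  e1 <- generate_erp_session(cfg, prof_sil, 2)
  e2 <- generate_erp_session(cfg, prof_sil, 2)
  expect_identical(e1, e2)
})

test_that("MUA event tables follow the stimulus design", {
  cfg <- sim_config(seed = 1, sample_rate = 250, n_stimuli = 10,
                    n_presentations = 25, stimulus_duration = 0.2)
  s <- generate_session(cfg, prof_sil, 0)
  expect_equal(nrow(s$events), 250)    # 25 repetitions of each of 10 songs
  per_stim <- s$events |>
    dplyr::group_by(stimulus) |>
    dplyr::summarise(ok = setequal(presentation, 1:25),
                     in_order = all(diff(presentation[order(trial)]) == 1))
  expect_true(all(per_stim$ok))
  expect_true(all(per_stim$in_order))
})

test_that("ERP sessions have 300 events over 8 quadrant channels", {
  cfg <- sim_config(seed = 1, sample_rate = 250, erp_n_stimuli = 3,
                    erp_n_presentations = 100)
  s <- generate_erp_session(cfg, prof_sil, 0)
  expect_equal(nrow(s$events), 300)    # 3 calls x 100 presentations
  expect_equal(nrow(s$channels), 8)
  expect_equal(as.integer(table(s$channels$hemisphere)), c(4L, 4L))
  expect_equal(as.integer(table(s$channels$position)), c(4L, 4L))
})

test_that("hemispheric gain and zero-signal configs behave as constructed", {
  # A = 0, g irrelevant: pure noise, ARM ~ 0 in expectation
  cfg0 <- sim_config(seed = 2, sample_rate = 400, baseline_noise_rms = 0.3,
                     evoked_amplitude = 0, adaptation_fraction = 0,
                     n_stimuli = 1, n_presentations = 50,
                     stimulus_duration = 0.2, n_channels_per_hemisphere = 1)
  arm0 <- compute_arm(generate_session(cfg0, prof_sil, 0))
  expect_lt(abs(mean(arm0$arm)), 4 * sd(arm0$arm) / sqrt(nrow(arm0)))

  # noiseless: per-trial evoked RMS on right channels is exactly g x left
  cfg <- sim_config(seed = 7, sample_rate = 400, baseline_noise_rms = 0,
                    evoked_amplitude = 1, adaptation_fraction = 0.08,
                    n_stimuli = 1, n_presentations = 10,
                    stimulus_duration = 0.2, n_channels_per_hemisphere = 1)
  prof_g <- lateralization_profile("Con-Env", g_high = 1.5)
  arm <- compute_arm(generate_session(cfg, prof_g, 1))
  wide <- tidyr::pivot_wider(arm[, c("hemisphere", "presentation", "arm")],
                             names_from = hemisphere, values_from = arm)
  expect_equal(wide$R / wide$L, rep(1.5, 10), tolerance = 1e-9)
  # and the decay law is (1-k)^(t-1)
  expect_equal(wide$L, (1 - 0.08)^(0:9), tolerance = 1e-9)
})

test_that("ERP caudal channels carry higher evoked gain than rostral", {
  cfg <- sim_config(seed = 3, sample_rate = 500, baseline_noise_rms = 0,
                    erp_n_presentations = 4)
  ea <- compute_earm(generate_erp_session(cfg, prof_sil, 1))
  by_pos <- ea |>
    dplyr::group_by(position) |>
    dplyr::summarise(m = mean(earm))
  expect_gt(by_pos$m[by_pos$position == "caudal"],
            by_pos$m[by_pos$position == "rostral"])
  # noiseless ERP is hemisphere-symmetric under g = 1
  sym <- ea |>
    dplyr::group_by(hemisphere) |>
    dplyr::summarise(m = mean(earm))
  expect_equal(sym$m[1], sym$m[2], tolerance = 1e-12)
})

test_that("invalid days and configs error clearly", {
  cfg <- sim_config(seed = 1, sample_rate = 250)
  expect_error(generate_session(cfg, prof_sil, 25), "span")
  expect_error(sim_config(sample_rate = -1), "sample_rate")
  expect_error(sim_config(adaptation_fraction = 1), "adaptation_fraction")
  expect_error(lateralization_profile("custom",
    breakpoints = tibble::tibble(day_from = c(0L, 3L), day_to = c(4L, 8L),
                                 gain = c(1, 2))), "overlap")
})

test_that("behavior logs follow the configured learning curve and balance", {
  # perfect learner: every trial correct, criterion at the first two blocks
  perfect <- generate_behavior_log(
    behavior_sim_config(seed = 1, p_correct_initial = 1, asymptote = 1),
    n_days = 2)
  expect_true(all(perfect$correct))
  det <- detect_criterion(perfect)
  expect_true(det$reached)
  expect_equal(det$block_reached, 2)

  # chance learner: expected block performance 50%, criterion never reached
  chance <- generate_behavior_log(
    behavior_sim_config(seed = 2, p_correct_initial = 0.5, asymptote = 0.5,
                        learning_rate = 0),
    n_days = 21)
  blocks <- score_blocks(chance)
  expect_lt(abs(mean(blocks$p_correct) - 0.5), 0.05)
  expect_false(detect_criterion(chance)$reached)

  # exact 25/25 Go/NoGo balance within every 50-trial block
  balance <- perfect |>
    dplyr::group_by(day, block = (trial - 1) %/% 50) |>
    dplyr::summarise(n_go = sum(type == "Go"), n = dplyr::n(),
                     .groups = "drop")
  expect_true(all(balance$n_go == 25 & balance$n == 50))
  # responded is consistent with type and correctness
  expect_true(all(chance$correct ==
                    ifelse(chance$type == "Go", chance$responded,
                           !chance$responded)))
  # i.i.d. mode is available and is not exactly balanced in general
  iid <- generate_behavior_log(
    behavior_sim_config(seed = 3, balanced_blocks = FALSE), n_days = 5)
  n_go <- sum(iid$type[1:50] == "Go")
  expect_true(n_go != 25 || sum(iid$type[51:100] == "Go") != 25)
})

test_that("amplitude_envelope recovers analytic envelopes", {
  fs <- 4000
  t <- (0:(2 * fs - 1)) / fs
  # constant-amplitude sinusoid -> envelope ~ a away from edges
  a <- 0.8
  x <- a * sin(2 * pi * 200 * t)
  env <- amplitude_envelope(x, smoothing_points = 21)
  interior <- seq(0.1 * fs, 1.9 * fs)
  expect_lt(max(abs(env[interior] - a)), 0.02 * a)
  expect_true(all(env >= 0))
  expect_length(env, length(x))

  # linear ramp 0 -> a on a carrier
  ramp <- a * t / max(t)
  env_r <- amplitude_envelope(ramp * sin(2 * pi * 200 * t),
                              smoothing_points = 21)
  expect_lt(max(abs(env_r[interior] - ramp[interior])), 0.05 * a)

  # default smoothing window is 500 points; needs >= 500 extrema
  fs2 <- 16000
  t2 <- (0:(2 * fs2 - 1)) / fs2
  x2 <- a * sin(2 * pi * 400 * t2)
  env_d <- amplitude_envelope(x2)
  expect_length(env_d, length(x2))
  expect_lt(max(abs(env_d[seq(0.1 * fs2, 1.9 * fs2)] - a)), 0.05 * a)

  # too few extrema for the spline
  expect_error(amplitude_envelope(seq(0, 1, length.out = 100)),
               "local maxima")
  expect_error(amplitude_envelope(x, smoothing_points = 1e6), "exceeds")
})

test_that("the envelope operator is near-idempotent on smooth envelopes", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  e <- 2 + 0.02 * sin(2 * pi * 50 * t)   # smooth, positive, dense extrema
  env <- amplitude_envelope(e, smoothing_points = 11)
  interior <- seq(0.1 * fs, 1.9 * fs)
  expect_lt(max(abs(env[interior] - e[interior])) / mean(e), 0.05)
})
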