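test_that("windowed_rms matches closed forms", {
  # constant trace
  expect_equal(windowed_rms(rep(-2.5, 100), c(0, 0.1), 1000), 2.5)
  # two samples 3, 4 -> sqrt((9+16)/2)
  expect_equal(windowed_rms(c(3, 4), c(0, 1), 2), sqrt(12.5))
  # unit sine over integer periods -> 1/sqrt(2) within discretization
  fs <- 1000
  x <- sin(2 * pi * 10 * (0:(fs - 1)) / fs)
  expect_equal(windowed_rms(x, c(0, 1), fs), 1 / sqrt(2), tolerance = 1e-6)
  # empty window errors
  expect_error(windowed_rms(1:10, c(0.5, 0.5), 10), "empty")
})

test_that("compute_arm returns the injected evoked RMS on noiseless sessions", {
  s <- make_const_session(amp = 0.7, gain_r = 1.5, n_stimuli = 2, n_pres = 4)
  arm <- compute_arm(s)
  expect_equal(nrow(arm), 2 * 8)
  expect_equal(arm$arm[arm$hemisphere == "L"], rep(0.7, 8), tolerance = 1e-12)
  expect_equal(arm$arm[arm$hemisphere == "R"], rep(1.05, 8), tolerance = 1e-12)
  expect_equal(arm$rms_base, rep(0, 16))
  expect_equal(arm$arm, arm$rms_stim - arm$rms_base)
})

test_that("baseline and stimulus windows have the specified sample counts", {
  fs <- 1000; dur <- 0.3
  expect_length(neurolat:::window_indices(0.6 - 0.5, 0.6, fs, 2000), 0.5 * fs)
  expect_length(neurolat:::window_indices(0.6, 0.6 + dur + 0.1, fs, 2000),
                (dur + 0.1) * fs)
  # half-open: baseline and stimulus windows share no sample
  b <- neurolat:::window_indices(0.1, 0.6, fs, 2000)
  st <- neurolat:::window_indices(0.6, 1.0, fs, 2000)
  expect_length(intersect(b, st), 0)
})

test_that("arm is scale-equivariant and shift-invariant", {
  s <- make_noise_session(n_trials = 10, seed = 4)
  arm1 <- compute_arm(s)
  s2 <- s; s2$traces <- 3.7 * s$traces
  expect_equal(compute_arm(s2)$arm, 3.7 * arm1$arm, tolerance = 1e-12)
  expect_equal(compute_arm(s2)$rms_stim, 3.7 * arm1$rms_stim,
               tolerance = 1e-12)
  # shift trace and events together by a whole-sample offset
  shift <- 0.1; ns <- round(shift * s$sample_rate)
  s3 <- s
  n_samp <- dim(s$traces)[3]
  s3$traces <- array(0, dim = dim(s$traces) + c(0, 0, ns))
  s3$traces[, , (ns + 1):(n_samp + ns)] <- s$traces
  s3$events$onset <- s3$events$onset + shift
  expect_equal(compute_arm(s3)$arm, arm1$arm, tolerance = 1e-12)
})

test_that("pure-noise arm has mean zero at CI level over many trials", {
  s <- make_noise_session(sigma = 0.5, n_trials = 1000, seed = 7)
  arm <- compute_arm(s)
  m <- mean(arm$arm); se <- sd(arm$arm) / sqrt(nrow(arm))
  expect_lt(abs(m), 4 * se)
  # matches the independent straight-loop oracle exactly
  oracle <- arm_oracle(s)
  merged <- dplyr::inner_join(
    arm, oracle, by = c("channel", "stimulus", "presentation"),
    suffix = c("", "_o"))
  expect_equal(merged$arm, merged$arm_o, tolerance = 1e-14)
})

test_that("events violating the window invariant are rejected", {
  s <- make_const_session()
  s$events$onset[2] <- 0.2   # < 0.5 s of pre-stimulus context
  expect_error(compute_arm(s), "window invariant")
})

test_that("mean_arm_early averages trials 2-6 and flags missing groups", {
  t1 <- arm_table(c(10, 2, 2, 2, 2, 2))
  expect_equal(mean_arm_early(t1)$mean_arm, 2)
  t2 <- arm_table(c(99, 5, 4, 3, 2, 1))  # t=2..6 are 5,4,3,2,1
  expect_equal(mean_arm_early(t2)$mean_arm, 3)
  # missing presentation 4 -> flagged, not dropped
  t3 <- dplyr::filter(t1, presentation != 4)
  r3 <- mean_arm_early(t3)
  expect_equal(nrow(r3), 1)
  expect_false(r3$complete)
  # random table matches a brute-force group-by mean
  set.seed(11)
  tbl <- tidyr::expand_grid(channel = c("a", "b"), stimulus = c("x", "y"),
                            presentation = 1:8) |>
    dplyr::mutate(arm = rnorm(dplyr::n()))
  got <- mean_arm_early(tbl) |> dplyr::arrange(channel, stimulus)
  want <- tbl |>
    dplyr::filter(presentation %in% 2:6) |>
    dplyr::group_by(channel, stimulus) |>
    dplyr::summarise(m = mean(arm), .groups = "drop") |>
    dplyr::arrange(channel, stimulus)
  expect_equal(got$mean_arm, want$m)
})

test_that("compute_earm averages waveforms before taking RMS", {
  prof <- lateralization_profile("Silence")
  cfg0 <- sim_config(seed = 5, sample_rate = 1000, baseline_noise_rms = 0,
                     evoked_amplitude = 0.8, erp_n_presentations = 6)
  ea <- compute_earm(generate_erp_session(cfg0, prof, 1))
  # noiseless: earm equals the configured evoked RMS times position gain
  expect_equal(ea$earm[ea$position == "caudal"], rep(0.8, 12),
               tolerance = 1e-12)
  expect_equal(ea$earm[ea$position == "rostral"], rep(0.8 * 0.4, 12),
               tolerance = 1e-12)
  expect_true(all(ea$n_trials_averaged == 6))

  # noisy: averaging order matters (earm != mean of per-trial ARMs)
  cfg1 <- sim_config(seed = 5, sample_rate = 1000, baseline_noise_rms = 0.5,
                     evoked_amplitude = 0.8, erp_n_presentations = 20)
  s1 <- generate_erp_session(cfg1, prof, 1)
  ea1 <- compute_earm(s1)
  per_trial <- compute_arm(s1) |>
    dplyr::group_by(channel, stimulus) |>
    dplyr::summarise(m = mean(arm), .groups = "drop")
  merged <- dplyr::inner_join(ea1, per_trial, by = c("channel", "stimulus"))
  expect_gt(max(abs(merged$earm - merged$m)), 1e-3)

  # noise averages out: more trials averaged -> smaller noise-only earm
  noise_earm <- function(n_pres, seed) {
    cfg <- sim_config(seed = seed, sample_rate = 500,
                      baseline_noise_rms = 0.5, evoked_amplitude = 0,
                      erp_n_stimuli = 1, erp_n_presentations = n_pres)
    mean(abs(compute_earm(generate_erp_session(cfg, prof, 1))$earm))
  }
  e25 <- vapply(1:8, function(s) noise_earm(25, s), numeric(1))
  e1 <- vapply(1:8, function(s) noise_earm(1, s), numeric(1))
  expect_lt(mean(e25), mean(e1))
})

test_that("earm caps averaging at the first 25 presentations", {
  prof <- lateralization_profile("Silence")
  cfg <- sim_config(seed = 2, sample_rate = 500, baseline_noise_rms = 0,
                    erp_n_presentations = 40)
  ea <- compute_earm(generate_erp_session(cfg, prof, 0))
  expect_true(all(ea$n_trials_averaged == 25))
})
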