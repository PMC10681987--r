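# Deterministic fixture sessions built in code.

# Noiseless session with a constant value in each stimulus-on window:
# per-trial ARM is exactly `amp * gain(hemisphere)`.
make_const_session <- function(amp = 1, fs = 1000, dur = 0.3, n_stimuli = 1,
                               n_pres = 3, gain_r = 1, subject = "s1",
                               day = 0L, condition = "Con-Env",
                               modality = "MUA") {
  pre <- 0.6; post <- 0.2
  n_samp <- round((pre + dur + post) * fs)
  n_trials <- n_stimuli * n_pres
  channels <- tibble::tibble(channel = c("chL", "chR"),
                             hemisphere = c("L", "R"),
                             position = c("caudal", "caudal"))
  events <- tibble::tibble(
    trial = seq_len(n_trials),
    stimulus = paste0("s", rep(seq_len(n_stimuli), each = n_pres)),
    onset = pre, duration = dur,
    presentation = rep(seq_len(n_pres), times = n_stimuli))
  idx <- (floor(pre * fs + 1e-9) + 1):floor((pre + dur + 0.1) * fs + 1e-9)
  traces <- array(0, dim = c(2, n_trials, n_samp))
  traces[1, , idx] <- amp
  traces[2, , idx] <- amp * gain_r
  recording_session(traces, fs, channels, events,
                    metadata = list(subject = subject, day = day,
                                    condition = condition,
                                    modality = modality))
}

# Pure-noise session (no evoked signal), one channel per hemisphere.
make_noise_session <- function(sigma = 0.5, fs = 400, dur = 0.2,
                               n_trials = 200, seed = 1) {
  set.seed(seed)
  pre <- 0.6; post <- 0.2
  n_samp <- round((pre + dur + post) * fs)
  channels <- tibble::tibble(channel = c("chL", "chR"),
                             hemisphere = c("L", "R"))
  events <- tibble::tibble(trial = seq_len(n_trials), stimulus = "s1",
                           onset = pre, duration = dur,
                           presentation = seq_len(n_trials))
  traces <- array(rnorm(2 * n_trials * n_samp, sd = sigma),
                  dim = c(2, n_trials, n_samp))
  recording_session(traces, fs, channels, events,
                    metadata = list(modality = "MUA"))
}

# Straight-loop ARM oracle, independent of compute_arm's vectorized path.
arm_oracle <- function(session, baseline_s = 0.5, post_s = 0.1) {
  fs <- session$sample_rate
  out <- list()
  for (i in seq_len(nrow(session$events))) {
    ev <- session$events[i, ]
    for (c in seq_len(nrow(session$channels))) {
      x <- session$traces[c, ev$trial, ]
      i_stim <- seq.int(floor(ev$onset * fs + 1e-9) + 1,
                        floor((ev$onset + ev$duration + post_s) * fs + 1e-9))
      i_base <- seq.int(floor((ev$onset - baseline_s) * fs + 1e-9) + 1,
                        floor(ev$onset * fs + 1e-9))
      out[[length(out) + 1]] <- tibble::tibble(
        channel = session$channels$channel[c], stimulus = ev$stimulus,
        presentation = ev$presentation,
        arm = sqrt(mean(x[i_stim]^2)) - sqrt(mean(x[i_base]^2)))
    }
  }
  dplyr::bind_rows(out)
}

# Closed-form OLS slope (explicit sums), the AdR regression oracle.
ols_slope_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Minimal arm table for adaptation tests: one channel/stimulus, given arms
# at presentations 1..length(arms).
arm_table <- function(arms, channel = "ch1", stimulus = "s1") {
  tibble::tibble(channel = channel, stimulus = stimulus,
                 presentation = seq_along(arms), arm = arms)
}
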