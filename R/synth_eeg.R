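# Analysis frequencies implied by the stimulus design: 1/0.247 s element
# onset asynchrony ~ 4.048 Hz, 1/0.494 s pair asynchrony ~ 2.024 Hz.
F_ELEMENT <- 4.048
F_PAIR <- 2.024

gaussian_bump <- function(t, mu, sd) exp(-0.5 * ((t - mu) / sd)^2)

# Canonical waveform kernels (unit peak), sampled at fs.
erp_kernel_wave <- function(fs) {
  t <- seq(0, 0.25, by = 1 / fs)
  -1.0 * gaussian_bump(t, 0.100, 0.020) + 0.6 * gaussian_bump(t, 0.185, 0.030)
}
mismatch_kernel_wave <- function(fs) {
  t <- seq(0, 0.30, by = 1 / fs)
  -gaussian_bump(t, 0.198, 0.015)   # peak inside the 173-223 ms window
}
congruence_kernel_wave <- function(fs) {
  t <- seq(0, 0.30, by = 1 / fs)
  -gaussian_bump(t, 0.155, 0.012)   # peak inside the 130-180 ms window
}

# Scalp topographies (unit maximum) on the projected montage.
topo_gauss <- function(montage, x0, y0, sd) {
  exp(-((montage$x - x0)^2 + (montage$y - y0)^2) / (2 * sd^2))
}
build_topographies <- function(montage) {
  list(
    erp = topo_gauss(montage, 0, 5, 15),                       # fronto-central
    mismatch = -topo_gauss(montage, 0, 15, 12) +               # anterior neg /
      0.8 * topo_gauss(montage, 0, -15, 12),                   # posterior pos
    congruence = topo_gauss(montage, -10, -8, 10),             # left centro-post.
    element = topo_gauss(montage, 0, 0, 18),                   # broad central
    pair = topo_gauss(montage, 15, -2, 12),                    # right lateral
    blink = exp(-sqrt((montage$x - montage$x[montage$name == "Fpz"])^2 +
                        (montage$y - montage$y[montage$name == "Fpz"])^2) / 15)
  )
}

#' Parameters of the synthetic EEG generator
#'
#' Defaults emulate the signal structure the analysis assumes: 1/f background
#' noise, tone-evoked responses, phase-locked oscillations at the element
#' (4.048 Hz) and pair (2.024 Hz) rates whose phase consistency (von Mises
#' concentration kappa) differs by timing condition -- and, at the pair rate,
#' grows from the first to the second experiment half in the beat-based
#' condition only -- deviant mismatch components peaking near 198 ms with an
#' anterior-posterior topography, a congruence component near 155 ms with a
#' left central-posterior topography applied only to temporally congruent
#' deviants, and frontal blink artifacts.
#'
#' @param sample_rate_hz Sampling rate of the generated recording (default
#'   1024; simulations in the test suite use 300 to match the analysis rate).
#' @param noise_scale RMS of the 1/f background noise per channel, in uV.
#' @param noise_1f_exponent Spectral exponent of the background noise.
#' @param erp_amp Peak amplitude of the tone-evoked kernel, uV.
#' @param mismatch_amp Peak amplitude of the deviant mismatch kernel, uV.
#' @param congruence_amp Peak amplitude of the congruence kernel added to
#'   temporally congruent deviants only, uV.
#' @param entrain_amp 2 x 3 matrix (rates `element`, `pair` by condition) of
#'   entrainment sinusoid amplitudes, uV.
#' @param entrain_kappa 2 x 3 x 2 array (rate x condition x half) of von Mises
#'   phase concentrations.
#' @param blink_rate_hz Poisson rate of blink events.
#' @param blink_amp Blink peak amplitude at Fpz, uV.
#' @param subject_sigma SD of the multiplicative log-normal subject random
#'   effect applied to all effect amplitudes by [synth_cohort()].
#' @param montage Montage data frame (default [standard_montage()]).
#' @return A list of class `oddbeat_eeg_params`.
#' @export
synth_eeg_params <- function(sample_rate_hz = 1024,
                             noise_scale = 5,
                             noise_1f_exponent = 1.0,
                             erp_amp = 0.8,
                             mismatch_amp = 5,
                             congruence_amp = 8,
                             entrain_amp = NULL,
                             entrain_kappa = NULL,
                             blink_rate_hz = 0.05,
                             blink_amp = 120,
                             subject_sigma = 0.2,
                             montage = standard_montage()) {
  conds <- timing_conditions()
  if (is.null(entrain_amp)) {
    entrain_amp <- rbind(element = c(5, 5, 5), pair = c(0.5, 0.5, 3))
    colnames(entrain_amp) <- conds
  }
  if (is.null(entrain_kappa)) {
    entrain_kappa <- array(0, dim = c(2, 3, 2),
                           dimnames = list(c("element", "pair"), conds,
                                           c("first", "second")))
    entrain_kappa["element", c("isochronous", "beat_based"), ] <- 30
    entrain_kappa["element", "interval_based", ] <- 0.3
    entrain_kappa["pair", , ] <- 0        # uniform phases: no coherence
    entrain_kappa["pair", "beat_based", "second"] <- 30
  }
  stopifnot(all(entrain_kappa >= 0), all(entrain_amp >= 0),
            noise_scale >= 0, "Fpz" %in% montage$name)
  structure(list(
    sample_rate_hz = sample_rate_hz,
    noise_scale = noise_scale,
    noise_1f_exponent = noise_1f_exponent,
    erp_amp = erp_amp,
    mismatch_amp = mismatch_amp,
    congruence_amp = congruence_amp,
    entrain_amp = entrain_amp,
    entrain_kappa = entrain_kappa,
    blink_rate_hz = blink_rate_hz,
    blink_amp = blink_amp,
    subject_sigma = subject_sigma,
    montage = montage,
    topographies = build_topographies(montage)
  ), class = "oddbeat_eeg_params")
}

# von Mises sampler (Best & Fisher 1979); kappa = 0 gives uniform phases.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

# 1/f noise: spectrally shaped noise, channels x samples. The spectrum is
# drawn directly as complex circular Gaussian (the FFT of white noise), so a
# single inverse FFT per channel suffices; taking the real part preserves
# Gaussianity and the target spectral shape.
one_over_f_noise <- function(n_samples, n_channels, fs, exponent, rms) {
  if (rms <= 0) return(matrix(0, n_channels, n_samples))
  m <- stats::nextn(n_samples, c(2, 3, 5))   # 5-smooth FFT length
  f <- seq_len(m) - 1L
  f <- pmin(f, m - f) * fs / m
  shape <- c(0, f[-1L]^(-exponent / 2))
  z <- matrix(complex(real = stats::rnorm(m * n_channels),
                      imaginary = stats::rnorm(m * n_channels)),
              m, n_channels)
  X <- Re(stats::mvfft(z * shape, inverse = TRUE)) / m
  X <- X[seq_len(n_samples), , drop = FALSE]
  scale <- rms / sqrt(colMeans(X^2))
  t(X) * scale   # channels x samples; per-channel scaling recycles by row
}

# Experiment half ("first"/"second") of each trial, within its condition.
trial_halves <- function(trials) {
  half <- character(nrow(trials))
  for (cond in unique(trials$condition)) {
    idx <- which(trials$condition == cond)
    half[idx] <- ifelse(seq_along(idx) <= length(idx) / 2, "first", "second")
  }
  half
}

#' Synthesize a multichannel EEG recording for a schedule
#'
#' Sums 1/f background noise, tone-evoked kernels on every tone, mismatch
#' kernels on deviants, congruence kernels on temporally congruent deviants
#' (ID deviants in interval-based trials, BD deviants in beat-based trials),
#' condition- and half-gated phase-locked sinusoids at the element and pair
#' rates, and blink artifacts. Fully determined by the seed.
#'
#' @param schedule An `oddbeat_schedule`.
#' @param params An `oddbeat_eeg_params` list.
#' @param seed Integer seed.
#' @return An `oddbeat_recording`: list with `data` (channels x samples, uV),
#'   `sample_rate_hz`, `channels`, `montage`, `events` (one row per tone, with
#'   `sample` indices), and `trials`.
#' @export
synth_recording <- function(schedule, params = synth_eeg_params(), seed = 1) {
  set.seed(as.integer(seed))
  fs <- params$sample_rate_hz
  mont <- params$montage
  n_ch <- nrow(mont)
  topo <- params$topographies
  trials <- schedule$trials
  total_dur <- max(trials$trial_onset_s + trials$trial_duration_s) + 1.0
  n <- ceiling(total_dur * fs)

  data <- one_over_f_noise(n, n_ch, fs, params$noise_1f_exponent,
                           params$noise_scale)

  events <- schedule_events(schedule)
  events$sample <- round(events$onset * fs) + 1L
  half <- trial_halves(trials)
  events$half <- half[events$trial_index + 1L]

  # Every source shares one scalp topography, so its whole contribution is a
  # rank-1 term: accumulate a scalar time course s(t) per source, then add
  # topo (x) s(t) in a single vectorized update.
  event_course <- function(samples, kernel, amps) {
    s <- numeric(n)
    nk <- length(kernel)
    for (e in seq_along(samples)) {
      idx <- samples[e] + seq_len(nk) - 1L
      keep <- idx <= n
      s[idx[keep]] <- s[idx[keep]] + amps[e] * kernel[keep]
    }
    s
  }

  # tone-evoked responses (quieter tones evoke smaller responses)
  if (params$erp_amp > 0) {
    s <- event_course(events$sample, erp_kernel_wave(fs),
                      params$erp_amp * 10^(events$level_db / 20))
    data <- data + topo$erp %o% s
  }
  # mismatch responses on deviants
  dev <- which(events$role %in% c("deviant_ID", "deviant_BD"))
  if (params$mismatch_amp > 0 && length(dev)) {
    s <- event_course(events$sample[dev], mismatch_kernel_wave(fs),
                      rep(params$mismatch_amp, length(dev)))
    data <- data + topo$mismatch %o% s
  }
  # congruence component on temporally congruent deviants only
  congr <- which((events$role == "deviant_ID" &
                    events$condition == "interval_based") |
                   (events$role == "deviant_BD" &
                      events$condition == "beat_based"))
  if (params$congruence_amp > 0 && length(congr)) {
    s <- event_course(events$sample[congr], congruence_kernel_wave(fs),
                      rep(params$congruence_amp, length(congr)))
    data <- data + topo$congruence %o% s
  }
  # phase-locked entrainment per trial
  freqs <- c(element = F_ELEMENT, pair = F_PAIR)
  for (r in c("element", "pair")) {
    if (all(params$entrain_amp[r, ] <= 0)) next
    s <- numeric(n)
    for (i in seq_len(nrow(trials))) {
      cond <- trials$condition[i]
      amp <- params$entrain_amp[r, cond]
      if (amp <= 0) next
      s0 <- round(trials$trial_onset_s[i] * fs) + 1L
      ns <- min(round(trials$trial_duration_s[i] * fs), n - s0 + 1L)
      tt <- (seq_len(ns) - 1L) / fs
      kappa <- params$entrain_kappa[r, cond, half[i]]
      ph <- rvonmises(1, 0, kappa)
      s[s0 + seq_len(ns) - 1L] <- amp * cos(2 * pi * freqs[[r]] * tt + ph)
    }
    data <- data + topo[[r]] %o% s
  }
  # blink artifacts
  if (params$blink_amp > 0 && params$blink_rate_hz > 0) {
    n_blinks <- stats::rpois(1, params$blink_rate_hz * total_dur)
    if (n_blinks > 0) {
      bt <- sort(stats::runif(n_blinks, 0, total_dur - 0.5))
      tb <- seq(0, 0.4, by = 1 / fs)
      bk <- gaussian_bump(tb, 0.12, 0.05) - 0.4 * gaussian_bump(tb, 0.28, 0.07)
      s <- event_course(round(bt * fs) + 1L, bk, rep(params$blink_amp,
                                                     length(bt)))
      data <- data + topo$blink %o% s
    }
  }

  structure(list(
    data = data,
    sample_rate_hz = fs,
    channels = mont$name,
    montage = mont,
    events = events,
    trials = trials
  ), class = "oddbeat_recording")
}

#' @export
print.oddbeat_recording <- function(x, ...) {
  cat("<oddbeat_recording>", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$sample_rate_hz, "Hz;", nrow(x$events), "events\n")
  invisible(x)
}

#' Parameters of the synthetic behavioral generator
#'
#' Defaults reproduce the qualitative pattern the analysis targets: lower hit
#' probability in the beat-based condition than in the isochronous and
#' interval-based conditions, log-normal reaction times, and a second-half RT
#' speed-up restricted to the beat-based condition.
#'
#' @param hit_prob Named hit probabilities per condition.
#' @param rt_meanlog 3 x 2 matrix (condition x half) of log-RT means
#'   (log seconds).
#' @param rt_sdlog Log-RT standard deviation.
#' @param lapse_prob Probability of a lapse (missed target regardless of
#'   condition).
#' @return List of class `oddbeat_behavior_params`.
#' @export
synth_behavior_params <- function(hit_prob = c(isochronous = 0.6775,
                                               interval_based = 0.6912,
                                               beat_based = 0.6388),
                                  rt_meanlog = NULL,
                                  rt_sdlog = 0.4,
                                  lapse_prob = 0.02) {
  conds <- timing_conditions()
  if (is.null(rt_meanlog)) {
    rt_meanlog <- cbind(first = log(c(0.511, 0.649, 0.700)),
                        second = log(c(0.511, 0.649, 0.600)))
    rownames(rt_meanlog) <- conds
  }
  stopifnot(all(hit_prob >= 0 & hit_prob <= 1),
            lapse_prob >= 0 && lapse_prob <= 1)
  structure(list(hit_prob = hit_prob, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog, lapse_prob = lapse_prob),
            class = "oddbeat_behavior_params")
}

#' Simulate behavioral responses to the repetition-detection task
#'
#' For every repetition trial draws a hit (condition-specific probability,
#' attenuated by the lapse probability) and, for hits, a log-normal reaction
#' time. RTs above 2 s occur in the tails, so the downstream RT filter is
#' exercised.
#'
#' @param schedule An `oddbeat_schedule`.
#' @param params An `oddbeat_behavior_params` list.
#' @param seed Integer seed.
#' @param subject Subject identifier stored in the table.
#' @return Tibble with one row per repetition trial: `subject`,
#'   `trial_index`, `condition`, `half`, `hit`, `rt_s` (NA unless hit).
#' @export
synth_behavior <- function(schedule, params = synth_behavior_params(),
                           seed = 1, subject = 1L) {
  set.seed(as.integer(seed))
  trials <- schedule$trials
  half <- trial_halves(trials)
  rep_idx <- which(trials$has_repetition)
  cond <- trials$condition[rep_idx]
  h <- half[rep_idx]
  p <- params$hit_prob[cond] * (1 - params$lapse_prob)
  hit <- stats::runif(length(rep_idx)) < p
  rt <- rep(NA_real_, length(rep_idx))
  if (any(hit)) {
    ml <- params$rt_meanlog[cbind(cond[hit], h[hit])]
    rt[hit] <- stats::rlnorm(sum(hit), ml, params$rt_sdlog)
  }
  tibble::tibble(subject = subject, trial_index = trials$trial_index[rep_idx],
                 condition = cond, half = h, hit = hit, rt_s = rt)
}

#' Simulate a cohort of subjects
#'
#' Generates per-subject schedules, EEG recordings and behavioral responses
#' with independent child seeds. Effect amplitudes (evoked, mismatch,
#' congruence, entrainment) receive a multiplicative log-normal subject random
#' effect with SD `params$subject_sigma`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param params `oddbeat_eeg_params`.
#' @param behavior_params `oddbeat_behavior_params`.
#' @param seed Master seed; child seeds are derived deterministically.
#' @param n_blocks,trials_per_block Schedule size per subject.
#' @return List of length `n_subjects`, each element a list with `subject`,
#'   `schedule`, `recording`, `responses`.
#' @export
synth_cohort <- function(n_subjects, params = synth_eeg_params(),
                         behavior_params = synth_behavior_params(),
                         seed = 1, n_blocks = 12L, trials_per_block = 20L) {
  stopifnot(n_subjects >= 2)
  lapply(seq_len(n_subjects), function(s) {
    child <- (as.integer(seed) + 7919L * s) %% 2147483647L
    set.seed(child)
    re <- exp(stats::rnorm(1, 0, params$subject_sigma))
    p <- params
    p$erp_amp <- p$erp_amp * re
    p$mismatch_amp <- p$mismatch_amp * re
    p$congruence_amp <- p$congruence_amp * re
    p$entrain_amp <- p$entrain_amp * re
    sched <- build_schedule(child, n_blocks, trials_per_block)
    rec <- synth_recording(sched, p, seed = child + 1L)
    resp <- synth_behavior(sched, behavior_params, seed = child + 2L,
                           subject = s)
    list(subject = s, schedule = sched, recording = rec, responses = resp)
  })
}
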