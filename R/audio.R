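#' Synthesize the audio waveform of one trial
#'
#' Each tone is rendered as a five-harmonic complex (amplitudes 1/h) at its
#' fundamental frequency, 166 ms long with 10 ms raised-cosine on/off ramps.
#' Tones at -10 dB are scaled by 10^(-10/20). The waveform ends at the offset
#' of the last tone.
#'
#' @param tones Tone table of a single trial (rows of `schedule$tones` for one
#'   `trial_index`).
#' @param sample_rate Audio sampling rate in Hz (>= 8000).
#' @param n_harmonics Number of harmonics (default 5).
#' @return Numeric waveform vector.
#' @export
synthesize_audio <- function(tones, sample_rate = 8000, n_harmonics = 5L) {
  if (sample_rate < 8000) stop("sample_rate must be >= 8 kHz")
  if (nrow(tones) == 0L)
    return(numeric(round(1.0 * sample_rate)))
  if (any(diff(tones$onset_s) <= 0)) stop("tone onsets must be increasing")
  n <- ceiling((max(tones$onset_s) + max(tones$duration_s)) * sample_rate)
  wav <- numeric(n)
  for (i in seq_len(nrow(tones))) {
    dur <- tones$duration_s[i]
    nt <- round(dur * sample_rate)
    t <- (seq_len(nt) - 1L) / sample_rate
    tone <- numeric(nt)
    for (h in seq_len(n_harmonics))
      tone <- tone + sin(2 * pi * h * tones$f0_hz[i] * t) / h
    tone <- tone * cos_ramp(nt, round(0.010 * sample_rate)) *
      10^(tones$level_db[i] / 20)
    i0 <- round(tones$onset_s[i] * sample_rate)
    idx <- i0 + seq_len(nt)
    idx <- idx[idx <= n]
    wav[idx] <- wav[idx] + tone[seq_along(idx)]
  }
  wav
}

# Raised-cosine on/off ramp envelope of length n with ramps of length nr.
cos_ramp <- function(n, nr) {
  env <- rep(1, n)
  if (nr > 0L && 2L * nr <= n) {
    r <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- r
    env[n + 1L - seq_len(nr)] <- r
  }
  env
}

#' Amplitude envelope via the analytic signal
#'
#' Modulus of the analytic (Hilbert) signal, computed in the frequency domain.
#'
#' @param x Numeric signal vector.
#' @return Envelope vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}
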