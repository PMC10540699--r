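# Zero-phase Butterworth filtering, applied in the frequency domain.
#
# A forward-backward (zero-phase) Butterworth pass has gain |H(f)|^2 and zero
# phase; we apply that gain directly to the spectrum, which is numerically
# stable at very low normalized cutoffs where the transfer-function form of
# the recursion breaks down. Signals are reflect-padded to suppress circular
# wrap-around.
butter_gain <- function(f, type, cutoff, order) {
  switch(type,
    lowpass = 1 / (1 + (f / cutoff)^(2 * order)),
    highpass = {
      g <- 1 / (1 + (cutoff / pmax(f, .Machine$double.xmin))^(2 * order))
      g[f == 0] <- 0
      g
    },
    bandstop = {
      f0sq <- cutoff[1] * cutoff[2]
      bw <- cutoff[2] - cutoff[1]
      om <- bw * f / (f0sq - f^2)
      om[abs(f0sq - f^2) < .Machine$double.eps] <- Inf
      1 / (1 + om^(2 * order))
    },
    stop("unknown filter type: ", type)
  )
}

# Indices continuing a boundary reflection beyond the end (or, reading
# right-to-left, before the start) of a length-n signal.
reflect_indices <- function(n, len, from = c("end", "start")) {
  from <- match.arg(from)
  if (len == 0L) return(integer(0))
  period <- 2L * (n - 1L)
  j <- (seq_len(len) - 1L) %% period + 1L
  if (from == "end") ifelse(j <= n - 1L, n - j, j - n + 2L)
  else rev(ifelse(j <= n - 1L, j + 1L, 2L * n - 1L - j))
}

#' Zero-phase Butterworth filter
#'
#' Applies the squared magnitude response of an order-`order` Butterworth
#' filter (the gain of a forward-backward pass) with zero phase shift.
#' Signals are reflect-padded (to a 5-smooth FFT length) before filtering.
#'
#' @param x Numeric vector, or matrix with time in rows (one column per
#'   channel).
#' @param fs Sampling rate, Hz.
#' @param type `"lowpass"`, `"highpass"` or `"bandstop"`.
#' @param cutoff Cutoff frequency in Hz (two values for `"bandstop"`).
#' @param order Filter order (default 5).
#' @return Filtered data, same shape as the input.
#' @export
zero_phase_butter <- function(x, fs, type, cutoff, order = 5) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (max(cutoff) >= fs / 2) stop("cutoff at or above Nyquist")
  n <- nrow(x)
  npad <- min(n - 1L, ceiling(3 * fs / min(cutoff)))
  np <- stats::nextn(n + 2L * npad, c(2, 3, 5))
  nright <- np - n - npad
  xp <- rbind(x[reflect_indices(n, npad, "start"), , drop = FALSE], x,
              x[reflect_indices(n, nright, "end"), , drop = FALSE])
  f <- (seq_len(np) - 1L)
  f <- pmin(f, np - f) * fs / np
  g <- butter_gain(f, type, cutoff, order)
  y <- Re(stats::mvfft(stats::mvfft(xp) * g, inverse = TRUE)) / np
  y <- y[npad + seq_len(n), , drop = FALSE]
  if (vec) drop(y) else y
}

# Fourier resampling (ideal zero-phase anti-aliasing + rate change). The
# input is reflect-extended to a multiple of the rate-ratio denominator so
# the output grid aligns exactly with the input start.
fft_resample <- function(x, fs, new_fs) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n0 <- nrow(x)
  g <- gcd_int(round(fs), round(new_fs))
  q <- round(fs) / g
  p <- round(new_fs) / g
  n <- as.integer(q * ceiling(n0 / q))
  if (n > n0)
    x <- rbind(x, x[reflect_indices(n0, n - n0, "end"), , drop = FALSE])
  n2 <- as.integer(n * p / q)
  X <- stats::mvfft(x)
  half <- min((n - 1L) %/% 2L, (n2 - 1L) %/% 2L)
  Y <- matrix(0+0i, n2, ncol(x))
  Y[1L, ] <- X[1L, ]
  if (half > 0L) {
    Y[1L + seq_len(half), ] <- X[1L + seq_len(half), ]
    Y[n2 + 1L - seq_len(half), ] <- X[n + 1L - seq_len(half), ]
  }
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  y <- y[seq_len(round(n0 * p / q)), , drop = FALSE]
  if (vec) drop(y) else y
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Continuous-data filter chain
#'
#' High-pass at 0.1 Hz, band-stop 48-52 Hz, resampling to `target_fs`
#' (default 300 Hz), then low-pass at 90 Hz; all zero-phase Butterworth of
#' order 5. Event sample indices are recomputed for the new rate.
#'
#' @param recording An `oddbeat_recording`.
#' @param target_fs Output sampling rate (default 300 Hz).
#' @param highpass,notch,lowpass Filter cutoffs in Hz.
#' @return The filtered, resampled recording.
#' @export
filter_chain <- function(recording, target_fs = 300, highpass = 0.1,
                         notch = c(48, 52), lowpass = 90) {
  fs <- recording$sample_rate_hz
  if (fs < 2 * max(lowpass, notch)) stop("sample rate below 2x highest cutoff")
  x <- t(recording$data)
  x <- zero_phase_butter(x, fs, "highpass", highpass)
  x <- zero_phase_butter(x, fs, "bandstop", notch)
  if (target_fs != fs) {
    x <- fft_resample(x, fs, target_fs)
    fs <- target_fs
  }
  x <- zero_phase_butter(x, fs, "lowpass", lowpass)
  recording$data <- t(x)
  recording$sample_rate_hz <- fs
  recording$events$sample <- round(recording$events$onset * fs) + 1L
  recording
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean over all channels from every channel, so
#' every sample has zero mean across the montage. Idempotent.
#'
#' @param recording An `oddbeat_recording`.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(recording) {
  if (nrow(recording$data) < 2L) stop("average reference needs >= 2 channels")
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}

# Peak detection with refractory period on a 1-10 Hz band-passed trace.
detect_blinks <- function(fpz, fs, refractory_s = 0.5) {
  bp <- zero_phase_butter(fpz, fs, "highpass", 1)
  bp <- zero_phase_butter(bp, fs, "lowpass", 10)
  thr <- stats::median(bp) + 3 * stats::mad(bp)
  above <- which(bp > thr)
  if (length(above) == 0L) return(integer(0))
  peaks <- integer(0)
  last <- -Inf
  for (i in above) {
    if (i > 1L && i < length(bp) && bp[i] >= bp[i - 1L] && bp[i] >= bp[i + 1L]
        && (i - last) > refractory_s * fs) {
      peaks <- c(peaks, i)
      last <- i
    }
  }
  peaks
}

#' Remove eyeblink artifacts
#'
#' Detects blinks on channel Fpz (1-10 Hz band-passed trace, peaks more than 3
#' scaled-MAD above the median, 500 ms refractory), averages blink-locked
#' epochs (-200 to +600 ms), and projects the top two spatiotemporal principal
#' components of that average out of all channels.
#'
#' @param recording An `oddbeat_recording` with an Fpz channel.
#' @param n_components Number of blink components to remove (default 2).
#' @return The cleaned recording; attribute `n_blinks` gives the number of
#'   detected blinks. If no blinks are found the data are returned unchanged
#'   with a warning.
#' @export
remove_blinks <- function(recording, n_components = 2L) {
  fs <- recording$sample_rate_hz
  ifpz <- match("Fpz", recording$channels)
  if (is.na(ifpz)) stop("channel Fpz not present")
  peaks <- detect_blinks(recording$data[ifpz, ], fs)
  rel <- round(-0.2 * fs):round(0.6 * fs)
  n <- ncol(recording$data)
  peaks <- peaks[peaks + min(rel) >= 1L & peaks + max(rel) <= n]
  if (length(peaks) == 0L) {
    warning("no blinks detected; returning data unchanged")
    attr(recording, "n_blinks") <- 0L
    return(recording)
  }
  avg <- matrix(0, nrow(recording$data), length(rel))
  for (p in peaks) avg <- avg + recording$data[, p + rel]
  avg <- avg / length(peaks)
  u <- svd(avg, nu = n_components, nv = 0)$u
  recording$data <- recording$data - u %*% (t(u) %*% recording$data)
  attr(recording, "n_blinks") <- length(peaks)
  recording
}

#' Epoch analyzed tones
#'
#' Cuts epochs around deviant and designated-standard tones (-50 to +247 ms by
#' default, inclusive endpoint) and baseline-corrects each epoch per channel
#' by the mean over -25 to +25 ms. Tones in scales containing a repetition are
#' excluded, as are events whose epoch would extend beyond the recording
#' (dropped with a warning).
#'
#' @param recording A (preprocessed) `oddbeat_recording`.
#' @param roles Event roles to epoch.
#' @param tmin,tmax Epoch limits in seconds relative to tone onset.
#' @param baseline Baseline window in seconds (NULL to skip).
#' @return An `oddbeat_epochs` object: `data` (trials x channels x time, uV),
#'   `times`, `sample_rate_hz`, `channels`, `montage`, `labels` (tibble with
#'   `content`, `condition`, `half`, `trial_index`, `role`).
#' @export
epoch_tones <- function(recording,
                        roles = c("deviant_ID", "deviant_BD",
                                  "designated_standard_ID",
                                  "designated_standard_BD"),
                        tmin = -0.050, tmax = 0.247,
                        baseline = c(-0.025, 0.025)) {
  fs <- recording$sample_rate_hz
  ev <- recording$events
  # discard scales containing a repetition
  rep_scales <- unique(ev[ev$role == "repetition",
                          c("trial_index", "scale_index")])
  keep <- ev$role %in% roles &
    !(paste(ev$trial_index, ev$scale_index) %in%
        paste(rep_scales$trial_index, rep_scales$scale_index))
  ev <- ev[keep, ]
  rel <- round(tmin * fs):round(tmax * fs)
  n <- ncol(recording$data)
  inb <- ev$sample + min(rel) >= 1L & ev$sample + max(rel) <= n
  if (any(!inb)) {
    warning(sum(!inb), " events beyond recording bounds skipped")
    ev <- ev[inb, ]
  }
  n_ep <- nrow(ev)
  dat <- array(0, dim = c(n_ep, nrow(recording$data), length(rel)))
  for (i in seq_len(n_ep))
    dat[i, , ] <- recording$data[, ev$sample[i] + rel]
  times <- rel / fs
  if (!is.null(baseline)) {
    bidx <- which(times >= baseline[1] - 1e-9 & times <= baseline[2] + 1e-9)
    bl <- apply(dat[, , bidx, drop = FALSE], c(1, 2), mean)
    dat <- dat - as.vector(bl)   # recycles over the time dimension
  }
  content <- c(deviant_ID = "deviant_ID", deviant_BD = "deviant_BD",
               designated_standard_ID = "standard_ID",
               designated_standard_BD = "standard_BD")[ev$role]
  structure(list(
    data = dat,
    times = times,
    sample_rate_hz = fs,
    channels = recording$channels,
    montage = recording$montage,
    labels = tibble::tibble(content = unname(content),
                            condition = ev$condition, half = ev$half,
                            trial_index = ev$trial_index, role = ev$role)
  ), class = "oddbeat_epochs")
}

#' @export
print.oddbeat_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<oddbeat_epochs>", d[1], "epochs x", d[2], "channels x", d[3],
      "samples @", x$sample_rate_hz, "Hz\n")
  invisible(x)
}

#' Denoising source separation (DSS)
#'
#' Linear components maximizing trial-reproducible (evoked) power: the data
#' are whitened by the total covariance (ridge-regularized), the principal
#' components of the trial-average covariance are extracted in the whitened
#' space, the top `n_keep` components are retained and projected back to
#' channel space. Dimensions are unchanged.
#'
#' @param epochs An `oddbeat_epochs` object.
#' @param n_keep Number of components retained (default 8).
#' @param ridge Ridge constant relative to the mean eigenvalue of the total
#'   covariance (default 1e-9).
#' @return The denoised epochs; attribute `dss_ratio` holds the evoked/total
#'   power ratio of each component.
#' @export
dss_denoise <- function(epochs, n_keep = 8L, ridge = 1e-9) {
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]; n_t <- d[3]
  if (n_ep < 2L) stop("DSS needs >= 2 trials")
  if (n_keep > n_ch) stop("n_keep exceeds channel count")
  m <- matrix(aperm(epochs$data, c(2, 1, 3)), n_ch, n_ep * n_t)
  c0 <- tcrossprod(m) / (n_ep * n_t)
  avg <- apply(epochs$data, c(2, 3), mean)
  c1 <- tcrossprod(avg) / n_t
  e0 <- eigen(c0, symmetric = TRUE)
  dvals <- pmax(e0$values, 0) + ridge * mean(e0$values)
  w <- e0$vectors %*% diag(1 / sqrt(dvals))
  e1 <- eigen(t(w) %*% c1 %*% w, symmetric = TRUE)
  unmix <- t(w %*% e1$vectors)            # components x channels
  mix <- solve(unmix)                      # channels x components
  total <- diag(unmix %*% c0 %*% t(unmix))
  evoked <- diag(unmix %*% c1 %*% t(unmix))
  proj <- mix[, seq_len(n_keep), drop = FALSE] %*%
    unmix[seq_len(n_keep), , drop = FALSE]
  m2 <- proj %*% m
  epochs$data <- aperm(array(m2, dim = c(n_ch, n_ep, n_t)), c(2, 1, 3))
  attr(epochs, "dss_ratio") <- evoked / total
  epochs
}

#' Robust trial averaging
#'
#' Iteratively re-weighted average over trials: residuals against the current
#' average are standardized per channel by the scaled median absolute
#' deviation, weighted by Tukey's bisquare (tuning constant 4.685), and the
#' weighted average is re-computed until the relative change falls below
#' `tol` (at most `max_iter` iterations). The average is then low-pass
#' filtered at `lowpass` Hz (zero-phase Butterworth, order 5).
#'
#' @param x Trials x channels x time array, or an `oddbeat_epochs` object.
#' @param fs Sampling rate (taken from the epochs object if given).
#' @param tuning Bisquare tuning constant.
#' @param max_iter,tol Iteration controls.
#' @param lowpass Final low-pass cutoff in Hz (NULL to skip).
#' @return Channels x time matrix of the robust average.
#' @export
robust_average <- function(x, fs = NULL, tuning = 4.685, max_iter = 10L,
                           tol = 1e-6, lowpass = 48) {
  if (inherits(x, "oddbeat_epochs")) {
    fs <- x$sample_rate_hz
    x <- x$data
  }
  d <- dim(x)
  if (d[1] < 2L) stop("robust averaging needs >= 2 trials")
  n <- d[1]; n_ch <- d[2]; m <- n_ch * d[3]
  xm <- matrix(x, n, m)                      # columns ordered channel-fastest
  ch_of_col <- rep(seq_len(n_ch), d[3])
  col_by_ch <- split(seq_len(m), ch_of_col)
  avg <- colMeans(xm)
  for (it in seq_len(max_iter)) {
    r <- abs(xm - rep(avg, each = n))
    # pool the residual scale per channel
    s <- vapply(col_by_ch, function(cols)
      stats::median(r[, cols]), numeric(1)) * 1.4826
    s[s < .Machine$double.eps] <- 1
    u <- r * rep(1 / (tuning * s[ch_of_col]), each = n)
    w <- (1 - pmin(u, 1)^2)^2
    sw <- colSums(w)
    new_avg <- colSums(w * xm) / pmax(sw, .Machine$double.eps)
    new_avg[sw == 0] <- avg[sw == 0]
    delta <- max(abs(new_avg - avg)) / max(max(abs(avg)), 1e-12)
    avg <- new_avg
    if (delta < tol) break
  }
  avg <- matrix(avg, n_ch, d[3])
  if (!is.null(lowpass)) {
    if (is.null(fs)) stop("fs required for the final low-pass")
    avg <- t(zero_phase_butter(t(avg), fs, "lowpass", lowpass))
  }
  avg
}
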