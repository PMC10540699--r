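# Filter chain, blink removal, referencing, epoching, DSS, robust averaging.

make_rec <- function(data, fs, events = NULL) {
  mont <- standard_montage()
  structure(list(data = data, sample_rate_hz = fs, channels = mont$name,
                 montage = mont,
                 events = events %||% tibble::tibble(onset = numeric(0),
                                                     sample = integer(0))),
            class = "oddbeat_recording")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the filter chain notches 50 Hz, removes DC, and is zero-phase", {
  fs <- 1024
  tt <- (0:(15 * fs - 1)) / fs
  x <- 10 + sin(2 * pi * 50 * tt) + cos(2 * pi * 4.048 * tt)
  rec <- make_rec(matrix(rep(x, each = 64), 64), fs,
                  tibble::tibble(onset = 1, sample = fs + 1L))
  out <- filter_chain(rec)
  expect_equal(out$sample_rate_hz, 300)
  y <- out$data[1, ]
  mid <- 1000:3500
  target <- cos(2 * pi * 4.048 * (seq_along(y) - 1) / 300)
  # 50 Hz and DC gone; 4.048 Hz survives at unit amplitude with zero lag
  resid <- y[mid] - target[mid]
  expect_lt(sqrt(mean(resid^2)), 0.02)
  cc <- stats::ccf(y[mid], target[mid], lag.max = 15, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(filter_chain(make_rec(matrix(0, 64, 100), 150)), "cutoff")
})

test_that("50 Hz attenuation through the band-stop exceeds 99%", {
  fs <- 1024
  x <- sin(2 * pi * 50 * (0:(10 * fs - 1)) / fs)
  y <- zero_phase_butter(x, fs, "bandstop", c(48, 52))
  expect_lt(max(abs(y[2000:8000])), 0.01)
})

test_that("filtering is linear and resampling preserves sinusoids", {
  fs <- 1024
  tt <- (0:(8 * fs - 1)) / fs
  a <- sin(2 * pi * 7 * tt); b <- sin(2 * pi * 23 * tt)
  fsum <- zero_phase_butter(a + b, fs, "lowpass", 90)
  fparts <- zero_phase_butter(a, fs, "lowpass", 90) +
    zero_phase_butter(b, fs, "lowpass", 90)
  expect_equal(fsum, fparts, tolerance = 1e-10)
  y <- oddbeat:::fft_resample(a, fs, 300)
  t2 <- (seq_along(y) - 1) / 300
  expect_equal(length(y), round(length(a) * 300 / 1024))
  expect_lt(max(abs(y[300:2000] - sin(2 * pi * 7 * t2[300:2000]))), 1e-3)
})

test_that("average referencing zeroes the channel mean and is idempotent", {
  set.seed(4)
  rec <- make_rec(matrix(rnorm(64 * 500), 64), 300)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  out2 <- rereference_average(out)
  expect_equal(out$data, out2$data)
  expect_error(rereference_average(make_rec(matrix(1, 1, 10), 300)),
               "2 channels")
})

test_that("blink removal projects out a rank-2 subspace and attenuates blinks", {
  sched <- build_schedule(31, n_blocks = 3L, trials_per_block = 2L)
  p <- synth_eeg_params(sample_rate_hz = 300, blink_rate_hz = 0.15,
                        blink_amp = 150)
  p0 <- p; p0$blink_rate_hz <- 0
  rec <- synth_recording(sched, p, seed = 4)
  rec0 <- synth_recording(sched, p0, seed = 4)
  cleaned <- remove_blinks(rec)
  expect_gt(attr(cleaned, "n_blinks"), 3)
  ifpz <- match("Fpz", rec$channels)
  blink_part <- rec$data[ifpz, ] - rec0$data[ifpz, ]
  pk <- which(blink_part > 0.7 * max(blink_part))   # blink-locked samples
  rms_before <- sqrt(mean(rec$data[ifpz, pk]^2))
  rms_after <- sqrt(mean(cleaned$data[ifpz, pk]^2))
  expect_gte(1 - rms_after / rms_before, 0.8)
  # removed subspace has rank 2
  diff <- rec$data - cleaned$data
  sv <- svd(diff, nu = 0, nv = 0)$d
  expect_lt(sv[3] / sv[1], 1e-10)
  # blink-free recording passes through unchanged
  expect_warning(same <- remove_blinks(rec0), "no blinks")
  expect_equal(same$data, rec0$data)
})

test_that("epoching yields 90 samples, baseline-corrects, and counts cells", {
  sched <- build_schedule(32, n_blocks = 3L, trials_per_block = 4L)
  p <- synth_eeg_params(sample_rate_hz = 300, blink_rate_hz = 0)
  rec <- synth_recording(sched, p, seed = 6)
  ep <- epoch_tones(rec)
  expect_equal(dim(ep$data)[3], 90L)
  expect_equal(dim(ep$data)[1], 4L * nrow(sched$trials))
  # 4 deviant_ID epochs per condition here (trials_per_block = 4, 1 block per
  # condition); the full design scales to 80 per condition
  counts <- table(ep$labels$content, ep$labels$condition)
  expect_true(all(counts == 4L))
  # baseline window has zero mean per epoch and channel
  bidx <- which(ep$times >= -0.025 - 1e-9 & ep$times <= 0.025 + 1e-9)
  bl <- apply(ep$data[, , bidx], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
  # constant channels become all-zero epochs
  rec$data[] <- 5
  ep2 <- epoch_tones(rec)
  expect_lt(max(abs(ep2$data)), 1e-12)
})

test_that("DSS ranks reproducible signal first and is lossless at full rank", {
  set.seed(7)
  n_tr <- 25; n_ch <- 64; n_t <- 90
  sig <- sin(2 * pi * 8 * (0:(n_t - 1)) / 300)
  mixing <- rnorm(n_ch)
  x <- array(rnorm(n_tr * n_ch * n_t), c(n_tr, n_ch, n_t))
  for (i in seq_len(n_tr)) x[i, , ] <- x[i, , ] + 3 * mixing %o% sig
  ep <- structure(list(data = x, times = (0:(n_t - 1)) / 300,
                       sample_rate_hz = 300,
                       channels = standard_montage()$name,
                       montage = standard_montage(),
                       labels = tibble::tibble(content = rep("a", n_tr))),
                  class = "oddbeat_epochs")
  dn <- dss_denoise(ep, n_keep = 8)
  expect_equal(dim(dn$data), dim(x))
  ratio <- attr(dn, "dss_ratio")
  avg <- apply(x, c(2, 3), mean)
  chan_ratio <- vapply(seq_len(n_ch), function(c)
    mean(avg[c, ]^2) / mean(x[, c, ]^2), numeric(1))
  expect_gt(max(ratio), max(chan_ratio))
  full <- dss_denoise(ep, n_keep = 64)
  expect_equal(full$data, x, tolerance = 1e-10)
  expect_error(dss_denoise(ep, n_keep = 65), "n_keep")
})

test_that("robust averaging equals the mean on clean data and resists outliers", {
  set.seed(8)
  n_tr <- 100; n_ch <- 4; n_t <- 30
  truth <- outer(rnorm(n_ch), sin(2 * pi * 5 * (0:(n_t - 1)) / 300))
  clean <- array(rnorm(n_tr * n_ch * n_t, sd = 0.5), c(n_tr, n_ch, n_t)) +
    rep(truth, each = n_tr)
  ra <- robust_average(clean, fs = 300, lowpass = NULL)
  pl <- apply(clean, c(2, 3), mean)
  se <- 0.5 / sqrt(n_tr)
  expect_lt(max(abs(ra - pl)), 2 * se)
  # identical trials: exactly the plain mean
  same <- array(rep(truth, each = 10), c(10, n_ch, n_t))
  expect_equal(robust_average(same, fs = 300, lowpass = NULL), truth)
  # one gross outlier trial: robust average stays near zero
  contaminated <- array(0, c(100, 1, 10))
  contaminated[100, , ] <- 1000
  ra2 <- robust_average(contaminated, fs = 300, lowpass = NULL)
  expect_lt(max(abs(ra2)), abs(mean(contaminated[, 1, 1])))
  expect_lt(max(abs(ra2)), 0.1)
})
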