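# ITPC machinery: formula values, DFT oracle equivalence, phase conventions,
# invariances, split-half bookkeeping, left-right flips, stimulus spectrum.

test_that("the coherence formula matches its printed anchor points", {
  expect_equal(itpc(rep(0.7, 80)), 80)
  expect_equal(itpc(2.1), 1)
  expect_equal(itpc(c(0, pi)), 0)
  # expectation 1 under uniform phases (Monte-Carlo, +-5%)
  set.seed(10)
  mc <- replicate(10000, itpc(stats::runif(80, -pi, pi)))
  expect_lt(abs(mean(mc) - 1), 0.05)
  # values bounded by [0, N]; normalized variant in [0, 1]
  expect_true(all(mc >= 0 & mc <= 80))
  expect_equal(itpc(rep(1.2, 40), normalized = TRUE), 1)
  expect_error(itpc(numeric(0)), "at least one")
})

test_that("coherence is invariant to a common phase rotation", {
  set.seed(11)
  ph <- stats::runif(50, -pi, pi)
  for (rot in c(0.5, 1.7, -2.9))
    expect_equal(itpc(ph), itpc((ph + rot + pi) %% (2 * pi) - pi))
})

test_that("exact-frequency DFT matches a zero-padded FFT bin", {
  set.seed(12)
  fs <- 300
  x <- rnorm(4110)
  # pad to 37500 samples so bin 507 sits exactly at 4.048 Hz
  xp <- c(x, numeric(37500 - length(x)))
  via_fft <- stats::fft(xp)[507]
  via_dft <- single_freq_dft(x, fs, 4.048)[1, 1]
  expect_lt(Mod(via_fft - via_dft) / Mod(via_dft), 1e-6)
  expect_error(single_freq_dft(x, fs, 200), "Nyquist")
})

test_that("DFT phase follows the cosine convention", {
  fs <- 300
  t <- (0:4199) / fs
  expect_equal(Arg(single_freq_dft(cos(2 * pi * 4.048 * t), fs, 4.048)[1, 1]),
               0, tolerance = 1e-2)
  expect_equal(Arg(single_freq_dft(sin(2 * pi * 4.048 * t), fs, 4.048)[1, 1]),
               -pi / 2, tolerance = 1e-2)
  # white-noise phases are uniform: no Rayleigh-style concentration
  set.seed(13)
  ph <- replicate(1000, Arg(single_freq_dft(rnorm(600), fs, 4.048)[1, 1]))
  expect_lt(itpc(ph) / length(ph), 0.01)  # resultant^2/N ~ 1/N under H0
})

test_that("peak tests compare targets against neighbor means", {
  set.seed(14)
  target <- rnorm(12, 3)
  nb <- cbind(target, target)   # neighbors equal target -> t = 0
  r0 <- peak_test(target, nb)
  expect_equal(r0$t, 0)
  r1 <- peak_test(target + 1, nb)
  expect_gt(r1$t, 0)            # target above neighbors -> positive t
  expect_lt(r1$p, 0.001)
  expect_error(peak_test(1, matrix(1, 1, 2)), "2 subjects")
})

test_that("left-right flips are involutions that fix the midline", {
  mont <- standard_montage()
  set.seed(15)
  v <- stats::setNames(rnorm(64), mont$name)
  f <- flip_lr(v, mont)
  expect_equal(flip_lr(f, mont), v)
  mid <- mont$name[mont$mirror == mont$name]
  expect_equal(f[mid], v[mid])
  expect_equal(unname(f["C4"]), unname(v["C3"]))
  # a left-lateralized map becomes right-lateralized
  v2 <- stats::setNames(numeric(64), mont$name); v2["C5"] <- 1
  expect_equal(names(which.max(flip_lr(v2, mont))), "C6")
})

test_that("split-half tests use per-half trial counts and FDR over 4 tests", {
  sched <- build_schedule(33, n_blocks = 6L, trials_per_block = 4L)
  p <- zero_effect_params()
  rec <- synth_recording(sched, p, seed = 16)
  ph <- sequence_phase(rec)
  tab <- itpc_maps(ph, halves = TRUE)
  expect_equal(nrow(tab), 6L)                    # 3 conditions x 2 halves
  expect_true(all(tab$n_trials == 4L))           # 8 per condition, 4 per half
  expect_true(all(vapply(tab$map, max, numeric(1)) <= 4L))

  # stationary synthetic locking shows the effect in both halves
  make_tab <- function(gap) {
    rows <- list()
    for (s in 1:8) for (h in c("first", "second")) for (j in 1:3) {
      base <- if (j == 3) 3 + gap[h] else 1
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = s, condition = timing_conditions()[j], half = h,
        rate = "pair", itpc = base + stats::rnorm(1, 0, 0.2))
    }
    do.call(rbind, rows)
  }
  set.seed(17)
  stat_tab <- make_tab(c(first = 0, second = 0))
  res <- split_half_tests(stat_tab)
  expect_true(all(res$p_fdr < 0.05))
  expect_true(all(res$p_fdr >= res$p))
})

test_that("the stimulus spectrum shows the condition-specific peaks", {
  sched <- build_schedule(34, n_blocks = 3L, trials_per_block = 4L)
  si <- stimulus_itpc(sched)
  f <- si$freqs[[1]]
  iel <- which(f == 4.048); ipr <- which(f == 2.024)
  iso <- si$itpc[[which(si$condition == "isochronous")]]
  beat <- si$itpc[[which(si$condition == "beat_based")]]
  iv <- si$itpc[[which(si$condition == "interval_based")]]
  expect_gt(iso[iel], iso[ipr])          # element rate dominates isochronous
  expect_gt(beat[ipr], iv[ipr])          # pair-rate peak only with fixed grid
  expect_gt(iso[iel] / si$n_trials[1], 0.5)  # strong coherence at 4.048 Hz
})
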