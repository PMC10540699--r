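# Stimulus-design generator: octave scales, onset rules, deviant/decoy
# placement, and the printed design counts.

test_that("scales span one octave as a geometric progression", {
  up <- build_scale(300, "ascending")
  expect_equal(up[1], 300)
  expect_equal(up[8], 600)
  expect_equal(up[4], 300 * 2^(3 / 7))  # ~404.1 Hz
  expect_equal(unique(round(diff(log2(up)), 12)), round(1 / 7, 12))
  down <- build_scale(600, "descending")
  expect_equal(down[8], 300)
  expect_error(build_scale(299, "ascending"), "300")
  expect_error(build_scale(601, "descending"), "300")
})

test_that("outlier frequencies sit 20% outside the scale range", {
  sc <- build_scale(300, "ascending")
  expect_equal(outlier_f0(sc, "higher"), 720)
  expect_equal(outlier_f0(sc, "lower"), 240)
  set.seed(1)
  for (i in 1:20) {
    o <- outlier_f0(sc)
    expect_true(o < min(sc) || o > max(sc))
  }
})

test_that("onset rules reproduce the element and pair grids", {
  set.seed(1)
  iso <- assign_onsets("isochronous")
  expect_equal(iso[11], 10 * 0.247)
  expect_equal(diff(iso), rep(0.247, 55))

  beat <- assign_onsets("beat_based")
  pair_initial <- beat[seq(1, 55, by = 2)]
  expect_equal(pair_initial, 0.494 * (0:27))
  gaps <- beat[seq(2, 56, by = 2)] - pair_initial
  expect_true(all(round(gaps / 0.247, 3) %in% jitter_multipliers()))

  iv <- assign_onsets("interval_based")
  expect_equal(iv[seq(2, 56, by = 2)] - iv[seq(1, 55, by = 2)],
               rep(0.247, 28))
  shifts <- diff(iv[seq(1, 55, by = 2)]) - 0.494
  expect_true(all(round(abs(shifts) / 0.247, 3) %in% c(0.166, 0.333)))
  expect_true(all(diff(iv) > 0))
})

test_that("jitter multipliers are symmetric about one", {
  m <- jitter_multipliers()
  expect_length(m, 4L)
  expect_equal(sort(1 - m[m < 1]), sort(m[m > 1] - 1))
})

test_that("a schedule reproduces every printed design count", {
  sched <- build_schedule(42)
  tn <- sched$tones
  expect_equal(nrow(sched$trials), 240L)
  expect_equal(nrow(tn), 13440L)
  expect_equal(unique(table(tn$trial_index)), 56L)
  expect_equal(unique(tn$duration_s), 0.166)
  # level: -10 dB iff odd 0-based position
  expect_equal(tn$level_db, ifelse(tn$position %% 2L == 1L, -10, 0))

  # one deviant of each type per trial, at the stated positions and scales
  for (role in c("deviant_ID", "deviant_BD")) {
    d <- tn[tn$role == role, ]
    expect_equal(nrow(d), 240L)
    expect_equal(unique(table(d$trial_index)), 1L)
    expect_equal(unique(d$position), if (role == "deviant_ID") 7L else 6L)
    expect_true(all(d$scale_index %in% 2:6))
    expect_equal(as.vector(table(d$condition)), rep(80L, 3))
  }
  # ID and BD deviants never share a scale
  dev <- tn[tn$role %in% c("deviant_ID", "deviant_BD"), ]
  expect_false(any(duplicated(dev[, c("trial_index", "scale_index")])))

  # designated standards: one per type per trial, in unaltered scales
  for (role in c("designated_standard_ID", "designated_standard_BD")) {
    d <- tn[tn$role == role, ]
    expect_equal(nrow(d), 240L)
    expect_equal(as.vector(table(d$condition)), rep(80L, 3))
  }
  # scale-category fractions: 4.5/7 unaltered, 1/7 per deviant type, 0.5/7 rep
  altered <- unique(tn[tn$role %in% c("deviant_ID", "deviant_BD",
                                      "repetition"),
                       c("trial_index", "scale_index")])
  expect_equal(1 - nrow(altered) / (240 * 7), 4.5 / 7)
  expect_equal(sum(sched$trials$has_repetition), 120L)
  # global deviant probability 2/56
  expect_equal(sum(tn$role %in% c("deviant_ID", "deviant_BD")) / nrow(tn),
               2 / 56)

  # blocks: 12 x 20, 4 per condition, no immediate condition repeats
  expect_equal(nrow(sched$blocks), 12L)
  expect_equal(as.vector(table(sched$blocks$condition)), rep(4L, 3))
  expect_true(all(sched$blocks$condition[-1] !=
                    sched$blocks$condition[-12]))
})

test_that("repetition scales contain an immediate repetition, disjoint from deviants", {
  sched <- build_schedule(7, n_blocks = 3, trials_per_block = 4)
  tn <- sched$tones
  reps <- tn[tn$role == "repetition", ]
  for (k in seq_len(nrow(reps))) {
    scale <- tn[tn$trial_index == reps$trial_index[k] &
                  tn$scale_index == reps$scale_index[k], ]
    expect_true(any(diff(scale$f0_hz) == 0))
    expect_true(all(scale$role %in% c("plain", "repetition")))
  }
})

test_that("every pre-target gap is exactly 247 ms in all conditions", {
  sched <- build_schedule(11, n_blocks = 3, trials_per_block = 4)
  tn <- sched$tones
  tg <- which(tn$role %in% c("deviant_ID", "deviant_BD",
                             "designated_standard_ID",
                             "designated_standard_BD"))
  expect_true(all(tn$position[tg] > 0))
  expect_equal(tn$onset_s[tg] - tn$onset_s[tg - 1L], rep(0.247, length(tg)))
  # onsets stay strictly increasing after the adjustment
  expect_true(all(unlist(lapply(split(tn$onset_s, tn$trial_index),
                                function(o) all(diff(o) > 0)))))
})

test_that("unaffected beat-based pair asynchronies equal 494 ms", {
  sched <- build_schedule(3, n_blocks = 6, trials_per_block = 4)
  gaps <- pair_onset_asynchronies(sched, "beat_based")
  expect_gt(length(gaps), 100)
  expect_equal(unique(round(gaps, 9)), 0.494)
})

test_that("event impulse trains peak at the element and pair rates", {
  sched <- build_schedule(5, n_blocks = 3, trials_per_block = 2)
  peak_freq <- function(onsets, band_lo, band_hi) {
    fs <- 1000
    n <- 2^20
    x <- numeric(n)
    x[round(onsets * fs) + 1L] <- 1
    spec <- Mod(stats::fft(x))[seq_len(n / 2)]
    f <- (seq_len(n / 2) - 1) * fs / n
    band <- f > band_lo & f < band_hi
    f[band][which.max(spec[band])]
  }
  iso <- sched$tones[sched$tones$condition == "isochronous" &
                       sched$tones$trial_index ==
                         min(sched$tones$trial_index[
                           sched$tones$condition == "isochronous"]), ]
  expect_equal(peak_freq(iso$onset_s, 3, 6), 1 / 0.247, tolerance = 1e-3)
  # pair-initial train under the beat-based generative rule (pre-override):
  # fundamental of the fixed pair grid
  set.seed(2)
  beat_onsets <- assign_onsets("beat_based")
  f0 <- peak_freq(beat_onsets[seq(1, 55, by = 2)], 1.5, 3)
  expect_equal(f0, 1 / 0.494, tolerance = 2e-3)
})

test_that("schedule generation is reproducible and deviant scales cover 2..6", {
  s1 <- build_schedule(123, n_blocks = 3, trials_per_block = 4)
  s2 <- build_schedule(123, n_blocks = 3, trials_per_block = 4)
  expect_identical(s1, s2)
  s3 <- build_schedule(124, n_blocks = 3, trials_per_block = 4)
  expect_false(identical(s1$tones$f0_hz, s3$tones$f0_hz))

  # empirical deviant-scale distribution is roughly uniform over {2..6}
  big <- build_schedule(99)   # 480 deviants
  dv <- big$tones$scale_index[big$tones$role %in%
                                c("deviant_ID", "deviant_BD")]
  counts <- table(factor(dv, levels = 2:6))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})
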