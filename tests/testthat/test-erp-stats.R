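# ANOVA maps, the planned congruence contrast, smoothing, cluster inference,
# post-hocs, and the subject-level indices.

mont64 <- standard_montage()

# Minimal per-subject ERP objects built directly from cell arrays.
make_erps <- function(w, contents = oddbeat:::ERP_CONTENTS) {
  structure(list(waveforms = w, times = (0:(dim(w)[4] - 1)) / 300 - 0.05,
                 sample_rate_hz = 300, channels = mont64$name,
                 montage = mont64, contents = contents,
                 conditions = timing_conditions()),
            class = "oddbeat_erps")
}

rand_erps_list <- function(n, sd = 1, n_t = 30, seed = 20,
                           contents = oddbeat:::ERP_CONTENTS) {
  set.seed(seed)
  lapply(seq_len(n), function(s) {
    w <- array(stats::rnorm(length(contents) * 3 * 64 * n_t, sd = sd),
               dim = c(length(contents), 3, 64, n_t),
               dimnames = list(contents, timing_conditions(), NULL, NULL))
    make_erps(w, contents)
  })
}

test_that("two-way F maps vanish for identical cells and match paired t^2", {
  erps <- rand_erps_list(8)
  # identical cells per subject -> F = 0 everywhere
  same <- lapply(erps, function(e) {
    for (i in 1:3) for (j in 1:3) e$waveforms[i, j, , ] <- e$waveforms[1, 1, , ]
    e
  })
  res <- anova_map(same, fwhm = 0)
  expect_lt(max(res$contents$F, res$time$F, res$interaction$F), 1e-10)

  # one content level shifted (with subject-varying magnitude) at one
  # channel/time: the two-way contents F equals the one-way oracle there
  erps2 <- rand_erps_list(8, seed = 21)
  erps2 <- lapply(seq_along(erps2), function(s) {
    e <- erps2[[s]]
    delta <- array(0, dim = c(64, 30))
    delta[5, 10] <- 2 + 0.5 * s   # varies across subjects
    for (j in 1:3) {
      e$waveforms["deviant_ID", j, , ] <- e$waveforms["standard", j, , ]
      e$waveforms["deviant_BD", j, , ] <-
        e$waveforms["standard", j, , ] + delta
    }
    e
  })
  res2 <- anova_map(erps2, fwhm = 0)
  y <- t(vapply(erps2, function(e)
    c(std = mean(e$waveforms["standard", , 5, 10]),
      bd = mean(e$waveforms["deviant_BD", , 5, 10])), numeric(2)))
  # contrast BD - standard carries the whole effect: F(2, 14) relates to the
  # t^2 of the pairwise difference via the one-way decomposition; check via
  # a direct one-way ANOVA oracle on the three content means
  y3 <- t(vapply(erps2, function(e)
    vapply(1:3, function(i) mean(e$waveforms[i, , 5, 10]), numeric(1)),
    numeric(3)))
  oracle <- rm_anova_oneway(y3)
  expect_equal(res2$contents$F[5, 10], oracle$F, tolerance = 1e-8)
  # F maps invariant to adding subject-specific constants to all cells
  shifted <- lapply(seq_along(erps2), function(s) {
    e <- erps2[[s]]
    e$waveforms <- e$waveforms + s * 10
    e
  })
  res3 <- anova_map(shifted, fwhm = 0)
  expect_equal(res3$contents$F, res2$contents$F, tolerance = 1e-6)
})

test_that("the congruence contrast is zero under additivity and antisymmetric", {
  erps <- rand_erps_list(6, seed = 22)
  # additive cells: mu + a_i + b_j -> subject contrast maps vanish (to
  # floating-point rounding of the cell sums)
  add <- lapply(erps, function(e) {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    for (i in 1:3) for (j in 1:3)
      e$waveforms[i, j, , ] <- a[i] + b[j]
    e
  })
  cg <- congruence_contrast(add, fwhm = 0)
  expect_lt(max(abs(cg$maps)), 1e-12)
  # identical deviant cells -> t exactly zero
  same <- lapply(erps, function(e) {
    for (i in 2:3) for (j in 1:3)
      e$waveforms[i, j, , ] <- e$waveforms[2, 1, , ]
    e
  })
  cg0 <- congruence_contrast(same, fwhm = 0)
  expect_true(all(cg0$t == 0))

  # swapping ID and BD flips the sign, keeps magnitude
  cg1 <- congruence_contrast(erps, fwhm = 0)
  swapped <- lapply(erps, function(e) {
    tmp <- e$waveforms["deviant_ID", , , ]
    e$waveforms["deviant_ID", , , ] <- e$waveforms["deviant_BD", , , ]
    e$waveforms["deviant_BD", , , ] <- tmp
    e
  })
  cg2 <- congruence_contrast(swapped, fwhm = 0)
  expect_equal(cg2$t, -cg1$t, tolerance = 1e-10)
})

test_that("topography smoothing conserves mass and respects its limits", {
  set.seed(23)
  v <- stats::rnorm(64)
  sm <- smooth_topo(v, mont64, fwhm = 5)
  expect_equal(sum(sm), sum(v), tolerance = 1e-6)
  # a delta spreads to neighbors
  d <- numeric(64); d[10] <- 1
  sd_ <- smooth_topo(d, mont64, fwhm = 5)
  expect_gt(max(sd_[-10]), 0)
  expect_lt(sd_[10], 1)
  expect_equal(sum(sd_), 1, tolerance = 1e-9)
  # constant maps and the zero-width limit pass through unchanged
  expect_equal(smooth_topo(rep(2, 64), mont64, 5), rep(2, 64),
               tolerance = 1e-9)
  expect_equal(smooth_topo(v, mont64, 0), v)
  m <- matrix(stats::rnorm(64 * 7), 64)
  expect_equal(colSums(smooth_topo_time(m, mont64)), colSums(m),
               tolerance = 1e-6)
})

test_that("cluster inference finds injected effects and respects thresholds", {
  set.seed(24)
  n <- 10
  maps <- array(stats::rnorm(n * 64 * 30), c(n, 64, 30))
  # inject a spatially contiguous effect at channels 1-4, times 10-15
  maps[, 1:4, 10:15] <- maps[, 1:4, 10:15] + 3
  cg <- oddbeat:::one_sample_stat(maps)
  res <- cluster_inference(cg, mont64, n_perm = 200, seed = 1)
  expect_gt(length(res$clusters), 0)
  expect_lt(min_cluster_p(res), 0.05)
  top <- res$clusters[[which.min(vapply(res$clusters, `[[`, numeric(1),
                                        "p_fwe"))]]
  expect_true(any(top$channels %in% 1:4))
  expect_true(any(top$times %in% 10:15))
  # threshold above the global max -> no clusters
  expect_length(oddbeat:::find_clusters(cg$F, max(cg$F) + 1,
                                        channel_adjacency(mont64)), 0)
  expect_error(cluster_inference(cg, mont64, n_perm = 50), "100")
})

test_that("post-hoc pairwise tests apply the stated Bonferroni factor", {
  set.seed(25)
  v <- matrix(stats::rnorm(30), 10, 3)
  ph <- posthoc_pairwise(v, labels = letters[1:3], n_comparisons = 3)
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_bonf, pmin(ph$p * 3, 1))
  same <- cbind(v[, 1], v[, 1], v[, 1])
  ph0 <- posthoc_pairwise(same, labels = letters[1:3])
  expect_true(all(ph0$t == 0) && all(ph0$p_bonf == 1))
})

test_that("subject indices are linear in the injected cell shifts", {
  erps <- rand_erps_list(5, sd = 0, n_t = 30, seed = 26)
  mask <- 1:64                     # first time point, all channels
  idx0 <- subject_indices(erps, mask, mask)
  expect_equal(idx0$mismatch_index, rep(0, 5))
  expect_equal(idx0$congruence_index, rep(0, 5))
  shifted <- lapply(erps, function(e) {
    e$waveforms["deviant_ID", "interval_based", , ] <-
      e$waveforms["deviant_ID", "interval_based", , ] - 0.6
    e$waveforms["deviant_BD", "beat_based", , ] <-
      e$waveforms["deviant_BD", "beat_based", , ] - 0.6
    e
  })
  idx1 <- subject_indices(shifted, mask, mask)
  expect_equal(idx1$congruence_index, rep(-0.6, 5))
  expect_error(subject_indices(erps, integer(0), mask), "empty")
})

test_that("the standards-only machinery needs split standards and stays null", {
  pooled <- rand_erps_list(6, seed = 27)
  expect_error(standards_control(pooled), "pool_standards")
  split4 <- rand_erps_list(8, seed = 28,
                           contents = c("standard_ID", "standard_BD",
                                        "deviant_ID", "deviant_BD"))
  res <- standards_control(split4, mont64, n_perm = 150, seed = 2)
  expect_gte(min_cluster_p(res), 0.05)   # pure noise: no significant cluster
})
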