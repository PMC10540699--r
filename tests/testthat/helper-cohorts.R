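# Shared simulation helpers: reduced-scale cohorts and their group analyses.
# Problem sizes here are the package's documented simulation conditions (see
# the methods vignette): recordings are generated at the 300 Hz analysis rate
# with shortened schedules, keeping the full analysis chain intact.

preprocess_subject <- function(rec) {
  if (rec$sample_rate_hz != 300) rec <- filter_chain(rec, target_fs = 300)
  rec <- suppressWarnings(remove_blinks(rec))
  rereference_average(rec)
}

# ERP-level cohort analysis: mismatch + congruence cluster statistics.
erp_cohort_analysis <- function(seed, n_subjects = 7, n_blocks = 3L,
                                trials_per_block = 4L,
                                eeg = synth_eeg_params(sample_rate_hz = 300),
                                n_perm = 100L, with_dss = TRUE,
                                standards_ctrl = FALSE) {
  cohort <- synth_cohort(n_subjects, eeg, seed = seed, n_blocks = n_blocks,
                         trials_per_block = trials_per_block)
  erps <- list(); erps_split <- list()
  for (s in seq_along(cohort)) {
    rec <- preprocess_subject(cohort[[s]]$recording)
    ep <- epoch_tones(rec)
    if (with_dss) ep <- dss_denoise(ep)
    erps[[s]] <- build_condition_erps(ep)
    if (standards_ctrl)
      erps_split[[s]] <- build_condition_erps(ep, pool_standards = FALSE)
  }
  mont <- eeg$montage
  mm <- mismatch_contrast(erps)
  cg <- congruence_contrast(erps)
  out <- list(
    times = erps[[1]]$times,
    erps = erps,
    mismatch = cluster_inference(mm, mont, n_perm, seed = seed + 101L),
    congruence = cluster_inference(cg, mont, n_perm, seed = seed + 102L))
  if (standards_ctrl)
    out$standards <- standards_control(erps_split, mont, n_perm,
                                       seed = seed + 103L)
  out
}

# ITPC-level cohort analysis: condition topography ANOVAs, split halves.
itpc_cohort_analysis <- function(seed, n_subjects = 7, n_blocks = 6L,
                                 trials_per_block = 4L,
                                 eeg = synth_eeg_params(sample_rate_hz = 300),
                                 n_perm = 100L) {
  cohort <- synth_cohort(n_subjects, eeg, seed = seed, n_blocks = n_blocks,
                         trials_per_block = trials_per_block)
  n <- length(cohort)
  mont <- eeg$montage
  conds <- timing_conditions()
  maps_el <- array(NA_real_, c(n, 3, nrow(mont)))
  maps_pr <- array(NA_real_, c(n, 3, nrow(mont)))
  sh <- list()
  for (s in seq_len(n)) {
    rec <- preprocess_subject(cohort[[s]]$recording)
    ph <- sequence_phase(rec)
    tab <- itpc_maps(ph)
    for (j in 1:3) {
      m <- tab$map[[which(tab$condition == conds[j])]]
      maps_el[s, j, ] <- m[, 5L]   # element rate column
      maps_pr[s, j, ] <- m[, 2L]   # pair rate column
    }
    tabh <- itpc_maps(ph, halves = TRUE)
    for (k in seq_len(nrow(tabh)))
      sh[[length(sh) + 1L]] <- tibble::tibble(
        subject = s, condition = tabh$condition[k], half = tabh$half[k],
        rate = c("pair", "element"),
        itpc = colMeans(tabh$map[[k]])[c(2L, 5L)])
  }
  list(
    element = condition_anova_topo(maps_el, mont, n_perm, seed = seed + 201L),
    pair = condition_anova_topo(maps_pr, mont, n_perm, seed = seed + 202L),
    split_half = split_half_tests(do.call(rbind, sh)),
    maps_element = maps_el, maps_pair = maps_pr)
}

# Combined cohort analysis: one cohort, both the ERP cluster statistics and
# the ITPC condition/split-half analyses (shared synthesis + preprocessing).
full_cohort_analysis <- function(seed, n_subjects = 8, n_blocks = 6L,
                                 trials_per_block = 4L,
                                 eeg = synth_eeg_params(sample_rate_hz = 300),
                                 n_perm = 100L) {
  cohort <- synth_cohort(n_subjects, eeg, seed = seed, n_blocks = n_blocks,
                         trials_per_block = trials_per_block)
  n <- length(cohort)
  mont <- eeg$montage
  conds <- timing_conditions()
  erps <- list()
  maps_el <- array(NA_real_, c(n, 3, nrow(mont)))
  maps_pr <- array(NA_real_, c(n, 3, nrow(mont)))
  sh <- list()
  for (s in seq_len(n)) {
    rec <- preprocess_subject(cohort[[s]]$recording)
    ph <- sequence_phase(rec)
    tab <- itpc_maps(ph)
    for (j in 1:3) {
      m <- tab$map[[which(tab$condition == conds[j])]]
      maps_el[s, j, ] <- m[, 5L]
      maps_pr[s, j, ] <- m[, 2L]
    }
    tabh <- itpc_maps(ph, halves = TRUE)
    for (k in seq_len(nrow(tabh)))
      sh[[length(sh) + 1L]] <- tibble::tibble(
        subject = s, condition = tabh$condition[k], half = tabh$half[k],
        rate = c("pair", "element"),
        itpc = colMeans(tabh$map[[k]])[c(2L, 5L)])
    ep <- dss_denoise(epoch_tones(rec))
    erps[[s]] <- build_condition_erps(ep)
  }
  mm <- mismatch_contrast(erps)
  cg <- congruence_contrast(erps)
  list(
    times = erps[[1]]$times,
    mismatch = cluster_inference(mm, mont, n_perm, seed = seed + 101L),
    congruence = cluster_inference(cg, mont, n_perm, seed = seed + 102L),
    element = condition_anova_topo(maps_el, mont, n_perm, seed = seed + 201L),
    pair = condition_anova_topo(maps_pr, mont, n_perm, seed = seed + 202L),
    split_half = split_half_tests(do.call(rbind, sh)))
}

# The four effect-recovery checks on a full cohort analysis.
recovery_checks <- function(res) {
  ph <- res$element$posthoc
  element_ok <- !is.null(ph) &&
    min_cluster_p(res$element$clusters) < 0.05 &&
    ph$p_bonf[ph$a == "isochronous" & ph$b == "interval_based"] < 0.05 &&
    ph$p_bonf[ph$a == "interval_based" & ph$b == "beat_based"] < 0.05 &&
    ph$p_bonf[ph$a == "isochronous" & ph$b == "beat_based"] > 0.05
  sh <- res$split_half
  split_ok <- sh$p_fdr[sh$rate == "pair" & sh$half == "first"] > 0.05 &&
    sh$p_fdr[sh$rate == "pair" & sh$half == "second"] < 0.05
  c(element = element_ok,
    split_half = split_ok,
    mismatch = cluster_overlaps_window(res$mismatch, res$times,
                                       c(0.173, 0.223)),
    congruence = cluster_overlaps_window(res$congruence, res$times,
                                         c(0.130, 0.180)))
}

# Does any familywise-significant cluster overlap the given time window (s)?
cluster_overlaps_window <- function(cl_res, times, window, alpha = 0.05) {
  for (cl in cl_res$clusters) {
    if (cl$p_fwe < alpha &&
        any(times[cl$times] >= window[1] & times[cl$times] <= window[2]))
      return(TRUE)
  }
  FALSE
}

zero_effect_params <- function(sample_rate_hz = 300) {
  synth_eeg_params(sample_rate_hz = sample_rate_hz, erp_amp = 0,
                   mismatch_amp = 0, congruence_amp = 0,
                   entrain_amp = matrix(0, 2, 3,
                                        dimnames = list(c("element", "pair"),
                                                        timing_conditions())),
                   blink_rate_hz = 0)
}
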