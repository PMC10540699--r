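EVENT_COLUMNS <- c("onset", "duration", "trial_type", "trial_index", "block",
                   "condition", "scale_index", "position", "f0_hz",
                   "level_db", "role")

#' Write an event table as tab-separated values
#'
#' BIDS-events conventions: onsets and durations in seconds, tab-separated,
#' UTF-8, missing values written as `"n/a"`.
#'
#' @param events Event tibble (e.g. from [schedule_events()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  miss <- setdiff(EVENT_COLUMNS, names(events))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(events)
  for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- "n/a"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path TSV file path.
#' @return Event tibble with `"n/a"` restored to NA.
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "n/a", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  miss <- setdiff(EVENT_COLUMNS, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' Serialize / restore a recording
#'
#' Recordings are runtime objects; they are serialized with R's native
#' format. The round trip is lossless for all fields.
#'
#' @param recording An `oddbeat_recording`.
#' @param path File path.
#' @return `write_recording` returns the path invisibly; `read_recording`
#'   returns the recording.
#' @export
write_recording <- function(recording, path) {
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "oddbeat_recording")) stop("not an oddbeat_recording")
  rec
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end run. Any field
#' can be overridden; probability thresholds must lie in (0, 1).
#'
#' @param seed Master seed (every stochastic stage derives a child seed).
#' @param n_subjects Cohort size.
#' @param n_blocks,trials_per_block Schedule size per subject.
#' @param sample_rate_hz Generator sampling rate.
#' @param n_perm Permutations for cluster inference.
#' @param forming_p Cluster-forming threshold.
#' @param alpha Familywise significance level.
#' @param fwhm Topography smoothing FWHM.
#' @param dss_keep DSS components kept.
#' @param eeg Optional list of overrides passed to [synth_eeg_params()].
#' @param behavior Optional list of overrides for [synth_behavior_params()].
#' @return Validated config list of class `oddbeat_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 4, n_blocks = 3L,
                            trials_per_block = 8L, sample_rate_hz = 300,
                            n_perm = 200L, forming_p = 0.001, alpha = 0.05,
                            fwhm = 5, dss_keep = 8L, eeg = list(),
                            behavior = list()) {
  cfg <- list(seed = as.integer(seed), n_subjects = n_subjects,
              n_blocks = n_blocks, trials_per_block = trials_per_block,
              sample_rate_hz = sample_rate_hz, n_perm = n_perm,
              forming_p = forming_p, alpha = alpha, fwhm = fwhm,
              dss_keep = dss_keep, eeg = eeg, behavior = behavior)
  for (th in c("forming_p", "alpha"))
    if (cfg[[th]] <= 0 || cfg[[th]] >= 1)
      stop("threshold `", th, "` must lie in (0, 1)")
  if (cfg$n_subjects < 2) stop("n_subjects must be >= 2")
  class(cfg) <- "oddbeat_config"
  cfg
}

# Fallback masks: canonical analysis windows over all channels, used for the
# subject indices when no cluster reaches significance at this run's scale.
window_nodes <- function(times, n_ch, window) {
  tidx <- which(times >= window[1] & times <= window[2])
  as.integer(outer(seq_len(n_ch), (tidx - 1L) * n_ch, "+"))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates schedules, EEG and behavior for a cohort, preprocesses each
#' subject (filter chain if needed, blink removal, average reference),
#' epochs and denoises, builds condition ERPs, and runs the group analyses:
#' ITPC peak tests, condition topography ANOVA and split-half tests, mismatch
#' and congruence cluster statistics, the standards-only control, behavioral
#' ANOVAs and the brain-behavior correlation report. Results and a manifest
#' are written to `out_dir` as JSON.
#'
#' @param config An `oddbeat_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  stopifnot(inherits(config, "oddbeat_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  eeg <- do.call(synth_eeg_params,
                 c(list(sample_rate_hz = config$sample_rate_hz), config$eeg))
  beh <- do.call(synth_behavior_params, config$behavior)
  cohort <- synth_cohort(config$n_subjects, eeg, beh, seed = config$seed,
                         n_blocks = config$n_blocks,
                         trials_per_block = config$trials_per_block)
  mont <- eeg$montage
  rs <- rate_spec()
  freqs <- c(rs$pair_neighbors[1], rs$pair_rate, rs$pair_neighbors[2],
             rs$element_neighbors[1], rs$element_rate, rs$element_neighbors[2])

  erps <- list(); erps_split <- list()
  itpc_all <- list(); itpc_halves <- list()
  responses <- list()
  for (s in seq_along(cohort)) {
    rec <- cohort[[s]]$recording
    if (rec$sample_rate_hz != 300) rec <- filter_chain(rec, target_fs = 300)
    rec <- tryCatch(remove_blinks(rec), warning = function(w) rec)
    rec <- rereference_average(rec)
    ph <- sequence_phase(rec, freqs)
    itpc_all[[s]] <- itpc_maps(ph)
    itpc_halves[[s]] <- itpc_maps(ph, halves = TRUE)
    ep <- epoch_tones(rec)
    ep <- dss_denoise(ep, n_keep = config$dss_keep)
    erps[[s]] <- build_condition_erps(ep)
    erps_split[[s]] <- build_condition_erps(ep, pool_standards = FALSE)
    responses[[s]] <- cohort[[s]]$responses
  }
  n <- length(cohort)
  conds <- timing_conditions()

  # --- spectral analysis ---
  # channel-averaged ITPC per subject x condition x frequency
  chan_avg <- function(tab, cond) colMeans(tab$map[[which(tab$condition ==
                                                            cond)]])
  peak_input <- function(fi_target, fi_nb) {
    tgt <- sapply(seq_len(n), function(s)
      mean(sapply(conds, function(cc) chan_avg(itpc_all[[s]], cc)[fi_target])))
    nb <- t(sapply(seq_len(n), function(s)
      rowMeans(sapply(conds, function(cc)
        chan_avg(itpc_all[[s]], cc)[fi_nb]))))
    list(target = tgt, neighbors = nb)
  }
  pe <- peak_input(5L, c(4L, 6L))
  pp <- peak_input(2L, c(1L, 3L))
  peaks <- list(element = peak_test(pe$target, pe$neighbors),
                pair = peak_test(pp$target, pp$neighbors))

  topo_maps <- function(fi) {
    m <- array(NA_real_, dim = c(n, 3, nrow(mont)))
    for (s in seq_len(n)) for (j in 1:3)
      m[s, j, ] <- itpc_all[[s]]$map[[which(itpc_all[[s]]$condition ==
                                              conds[j])]][, fi]
    m
  }
  itpc_anova <- list(
    element = condition_anova_topo(topo_maps(5L), mont, config$n_perm,
                                   config$forming_p, config$fwhm,
                                   seed = config$seed + 11L),
    pair = condition_anova_topo(topo_maps(2L), mont, config$n_perm,
                                config$forming_p, config$fwhm,
                                seed = config$seed + 12L))

  sh <- list()
  for (s in seq_len(n)) {
    tab <- itpc_halves[[s]]
    for (k in seq_len(nrow(tab)))
      sh[[length(sh) + 1L]] <- tibble::tibble(
        subject = s, condition = tab$condition[k], half = tab$half[k],
        rate = c("pair", "element"),
        itpc = colMeans(tab$map[[k]])[c(2L, 5L)])
  }
  split_half <- split_half_tests(do.call(rbind, sh))

  # --- ERP statistics ---
  anova_maps <- anova_map(erps, fwhm = config$fwhm)
  mm <- mismatch_contrast(erps, fwhm = config$fwhm)
  cg <- congruence_contrast(erps, fwhm = config$fwhm)
  mm_cl <- cluster_inference(mm, mont, config$n_perm, config$forming_p,
                             seed = config$seed + 21L)
  cg_cl <- cluster_inference(cg, mont, config$n_perm, config$forming_p,
                             seed = config$seed + 22L)
  ctrl_cl <- standards_control(erps_split, mont, config$n_perm,
                               config$forming_p, config$fwhm,
                               seed = config$seed + 23L)
  times <- erps[[1]]$times
  mm_mask <- cluster_mask(mm_cl, config$alpha,
                          window_nodes(times, nrow(mont), c(0.173, 0.223)))
  cg_mask <- cluster_mask(cg_cl, config$alpha,
                          window_nodes(times, nrow(mont), c(0.130, 0.180)))
  erp_idx <- subject_indices(erps, mm_mask, cg_mask)

  # --- behavior ---
  resp <- do.call(rbind, responses)
  scored <- score_and_filter(resp)
  acc <- sapply(conds, function(cc)
    scored$accuracy[match(paste(seq_len(n), cc),
                          paste(scored$subject, scored$condition))])
  beh_anova <- rm_anova_time(acc)
  scored_h <- score_and_filter(resp, by_half = TRUE)
  halves <- halves_tests(scored_h)

  # --- brain-behavior indices ---
  itpc_index <- sapply(seq_len(n), function(s) {
    tab <- itpc_halves[[s]]
    g <- function(cc) colMeans(tab$map[[which(tab$condition == cc &
                                                tab$half == "second")]])[2L]
    g("interval_based") - g("beat_based")
  })
  indices <- tibble::tibble(
    subject = seq_len(n),
    behavioral_index = acc[, "interval_based"] - acc[, "beat_based"],
    itpc_index = itpc_index,
    congruence_index = erp_idx$congruence_index,
    mismatch_index = erp_idx$mismatch_index)
  # the correlation analysis needs >= 5 complete rows; skip on tiny cohorts
  bb <- if (n >= 5L) brain_behavior(indices)
        else list(excluded = integer(0), correlations = NULL)

  results <- list(
    config = unclass(config),
    peaks = peaks,
    itpc_anova = lapply(itpc_anova, function(a)
      list(F_max = max(a$F), df = a$df,
           min_p_fwe = min_cluster_p(a$clusters))),
    split_half = split_half,
    erp = list(
      interaction_F_max = max(anova_maps$interaction$F),
      mismatch = list(F_max = max(mm$F), min_p_fwe = min_cluster_p(mm_cl)),
      congruence = list(F_max = max(cg$F), min_p_fwe = min_cluster_p(cg_cl)),
      standards_control_min_p_fwe = min_cluster_p(ctrl_cl)),
    behavior = list(F = beh_anova$F, p = beh_anova$p,
                    posthoc = beh_anova$posthoc, halves = halves),
    brain_behavior = list(excluded = bb$excluded,
                          correlations = bb$correlations),
    indices = indices
  )
  jsonlite::write_json(results, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_events(schedule_events(cohort[[1]]$schedule),
               file.path(out_dir, "events_subject1.tsv"))
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    outputs = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}
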