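#' Analysis rates and neighbor frequencies
#'
#' The element presentation rate (1/0.247 s ~ 4.048 Hz), the pair rate
#' (1/0.494 s ~ 2.024 Hz), and the neighboring frequencies each peak is tested
#' against.
#'
#' @return List with `element_rate`, `pair_rate`, `element_neighbors`,
#'   `pair_neighbors` (Hz).
#' @export
rate_spec <- function() {
  list(element_rate = 4.048, pair_rate = 2.024,
       element_neighbors = c(3.974, 4.124),
       pair_neighbors = c(1.949, 2.099))
}

#' Single-frequency discrete Fourier transform
#'
#' Complex Fourier coefficient at arbitrary (not bin-gridded) frequencies, as
#' the inner product of the signal with a complex exponential. A pure cosine
#' yields phase 0; a pure sine yields phase -pi/2.
#'
#' @param x Numeric vector, or matrix with time in rows (columns = channels).
#' @param fs Sampling rate, Hz.
#' @param freqs Frequencies to evaluate, Hz (must be below Nyquist).
#' @return Complex matrix channels x frequencies (a vector input gives a
#'   1-row matrix).
#' @export
single_freq_dft <- function(x, fs, freqs) {
  if (any(freqs > fs / 2)) stop("requested frequency above Nyquist")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  t <- (seq_len(n) - 1L) / fs
  basis <- exp(-2i * pi * outer(t, freqs))      # n x f
  t(x) %*% basis                                 # channels x frequencies
}

#' Fourier phase of whole-sequence epochs
#'
#' For every trial, extracts the recording segment from sequence onset to
#' offset and evaluates the exact-frequency DFT phase per channel at the
#' requested frequencies. Trials of different lengths are analyzed over their
#' own full duration.
#'
#' @param recording A (preprocessed) `oddbeat_recording` whose `trials` table
#'   carries sequence onsets and durations.
#' @param freqs Frequencies in Hz (default: rates and neighbors from
#'   [rate_spec()]).
#' @return List with `phases` (array trials x channels x frequencies),
#'   `freqs`, and `meta` (tibble: trial_index, condition, half).
#' @export
sequence_phase <- function(recording, freqs = NULL) {
  if (is.null(freqs)) {
    rs <- rate_spec()
    freqs <- c(rs$pair_neighbors[1], rs$pair_rate, rs$pair_neighbors[2],
               rs$element_neighbors[1], rs$element_rate,
               rs$element_neighbors[2])
  }
  fs <- recording$sample_rate_hz
  trials <- recording$trials
  n_ch <- nrow(recording$data)
  ph <- array(NA_real_, dim = c(nrow(trials), n_ch, length(freqs)))
  for (i in seq_len(nrow(trials))) {
    s0 <- round(trials$trial_onset_s[i] * fs) + 1L
    ns <- round(trials$trial_duration_s[i] * fs)
    seg <- t(recording$data[, s0 + seq_len(ns) - 1L, drop = FALSE])
    ph[i, , ] <- Arg(single_freq_dft(seg, fs, freqs))
  }
  list(phases = ph, freqs = freqs,
       meta = tibble::tibble(trial_index = trials$trial_index,
                             condition = trials$condition,
                             half = trial_halves(trials)))
}

#' Inter-trial phase coherence
#'
#' `([sum cos phi]^2 + [sum sin phi]^2) / N` over the `N` trials, ranging from
#' the uniform-phase expectation 1 to `N` at perfect coherence. With
#' `normalized = TRUE` the conventional resultant length `|mean exp(i phi)|`
#' in \[0, 1\] is returned instead (a monotone transform at fixed N).
#'
#' @param phases Numeric vector of phases (radians).
#' @param normalized Return the unit-normalized resultant length instead.
#' @return Scalar coherence value.
#' @export
itpc <- function(phases, normalized = FALSE) {
  n <- length(phases)
  if (n < 1L) stop("itpc needs at least one phase")
  v <- (sum(cos(phases))^2 + sum(sin(phases))^2) / n
  if (normalized) sqrt(v / n) else v
}

# ITPC over the first dimension of a trials x channels x freqs phase array.
itpc_array <- function(ph, normalized = FALSE) {
  n <- dim(ph)[1]
  cs <- apply(cos(ph), c(2, 3), sum)
  sn <- apply(sin(ph), c(2, 3), sum)
  v <- (cs^2 + sn^2) / n
  if (normalized) sqrt(v / n) else v
}

#' Condition-wise ITPC maps
#'
#' ITPC per channel and frequency, computed separately per timing condition
#' and optionally per experiment half. ITPC is always computed per channel
#' first; channel averaging (if any) happens downstream.
#'
#' @param phase_obj Output of [sequence_phase()].
#' @param halves Split into experiment halves as well (default FALSE).
#' @param normalized Passed to the coherence computation.
#' @return Tibble with columns condition, half, n_trials, and a `map` list
#'   column of channels x frequencies matrices.
#' @export
itpc_maps <- function(phase_obj, halves = FALSE, normalized = FALSE) {
  meta <- phase_obj$meta
  groups <- if (halves) {
    unique(meta[, c("condition", "half")])
  } else {
    g <- unique(meta[, "condition", drop = FALSE])
    g$half <- "all"
    g
  }
  maps <- vector("list", nrow(groups))
  n_trials <- integer(nrow(groups))
  for (k in seq_len(nrow(groups))) {
    sel <- meta$condition == groups$condition[k] &
      (groups$half[k] == "all" | meta$half == groups$half[k])
    n_trials[k] <- sum(sel)
    maps[[k]] <- itpc_array(phase_obj$phases[sel, , , drop = FALSE],
                            normalized)
  }
  out <- tibble::as_tibble(groups)
  out$n_trials <- n_trials
  out$map <- maps
  out
}

#' Spectral peak test against neighboring frequencies
#'
#' Paired t-test, across subjects, of channel-averaged ITPC at a target
#' frequency against the mean of its two neighboring frequencies. Positive t
#' means the target exceeds its neighbors.
#'
#' @param target Per-subject ITPC at the target frequency.
#' @param neighbors Subjects x 2 matrix of neighbor ITPC values.
#' @return List with `t`, `df`, `p`, and the mean difference `delta`.
#' @export
peak_test <- function(target, neighbors) {
  neighbors <- as.matrix(neighbors)
  if (length(target) < 2L) stop("need >= 2 subjects")
  d <- target - rowMeans(neighbors)
  if (stats::sd(d) < 1e-12) {
    # degenerate: constant difference across subjects
    tt <- if (abs(mean(d)) < 1e-12) list(t = 0, df = length(d) - 1, p = 1)
          else list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0)
    return(c(tt, list(delta = mean(d))))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       delta = mean(d))
}

#' Topographic condition ANOVA on ITPC maps with cluster correction
#'
#' Smooths each subject-by-condition channel topography, computes a
#' per-channel one-way repeated-measures F for the timing-condition factor,
#' and corrects over channels by permutation: condition labels are permuted
#' within subject and the null distribution of the maximum suprathreshold
#' cluster mass (spatial adjacency) calibrates familywise cluster p-values.
#'
#' @param maps Array subjects x conditions x channels (conditions in
#'   [timing_conditions()] order).
#' @param montage Montage data frame.
#' @param n_perm Number of permutations (>= 100).
#' @param forming_p Cluster-forming p threshold (default 0.001).
#' @param fwhm Topography smoothing FWHM (projection units).
#' @param seed RNG seed for the permutations.
#' @return List with `F` (per channel), `df`, `clusters`
#'   (an `oddbeat_clusters`), and the post-hoc paired t-tests on
#'   cluster-averaged values (Bonferroni over 3 comparisons), or NULL if no
#'   cluster is significant.
#' @export
condition_anova_topo <- function(maps, montage = standard_montage(),
                                 n_perm = 200L, forming_p = 0.001,
                                 fwhm = 5, seed = 1) {
  n <- dim(maps)[1]; k <- dim(maps)[2]
  if (k != 3L) stop("expected 3 timing conditions")
  for (s in seq_len(n))
    for (j in seq_len(k))
      maps[s, j, ] <- smooth_topo(maps[s, j, ], montage, fwhm)
  res <- rm_anova_oneway(maps)
  thr <- stats::qf(1 - forming_p, res$df[1], res$df[2])
  adj <- channel_adjacency(montage)
  set.seed(as.integer(seed))
  perms <- lapply(seq_len(n_perm), function(i)
    t(vapply(seq_len(n), function(s) sample(k), integer(k))))
  perm_fun <- function(i) {
    mp <- maps
    for (s in seq_len(n)) mp[s, , ] <- maps[s, perms[[i]][s, ], ]
    matrix(rm_anova_oneway(mp)$F, ncol = 1L)
  }
  cl <- cluster_inference_generic(matrix(res$F, ncol = 1L), thr, adj,
                                  perm_fun, n_perm)
  posthoc <- NULL
  sig <- Filter(function(c) c$p_fwe < 0.05, cl$clusters)
  if (length(sig) > 0L) {
    chans <- sort(unique(unlist(lapply(sig, `[[`, "channels"))))
    vals <- apply(maps[, , chans, drop = FALSE], c(1, 2), mean)
    posthoc <- posthoc_pairwise(vals, labels = timing_conditions(),
                                n_comparisons = 3L)
  }
  list(F = res$F, df = res$df, clusters = cl, posthoc = posthoc)
}

#' Split-half condition tests of channel-averaged ITPC
#'
#' For each rate and experiment half, a one-way repeated-measures ANOVA of
#' channel-averaged ITPC over the three timing conditions; the four resulting
#' p-values (2 rates x 2 halves) are FDR-corrected (Benjamini-Hochberg).
#'
#' @param tab Tibble with columns `subject`, `rate` (`"element"`/`"pair"`),
#'   `half` (`"first"`/`"second"`), `condition`, `itpc` (channel-averaged).
#' @return Tibble with one row per rate x half: F, df, p, p_fdr.
#' @export
split_half_tests <- function(tab) {
  conds <- timing_conditions()
  cells <- expand.grid(rate = unique(tab$rate), half = c("first", "second"),
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    sub <- tab[tab$rate == cells$rate[k] & tab$half == cells$half[k], ]
    subj <- sort(unique(sub$subject))
    y <- matrix(NA_real_, length(subj), length(conds))
    for (j in seq_along(conds))
      y[, j] <- sub$itpc[match(paste(subj, conds[j]),
                               paste(sub$subject, sub$condition))]
    if (anyNA(y)) stop("missing subject x condition cells in split-half data")
    r <- rm_anova_oneway(y)
    out[[k]] <- tibble::tibble(rate = cells$rate[k], half = cells$half[k],
                               F = r$F, df1 = r$df[1], df2 = r$df[2], p = r$p)
  }
  res <- do.call(rbind, out)
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' ITPC spectrum of the stimulus
#'
#' Applies the ITPC machinery to the stimulus itself: each trial's audio is
#' synthesized, its Hilbert amplitude envelope extracted (mean removed), and
#' the exact-frequency DFT phase pooled across trials per condition.
#'
#' @param schedule An `oddbeat_schedule`.
#' @param freqs Frequencies in Hz (default as in [sequence_phase()]).
#' @param sample_rate Audio sampling rate (default 8000).
#' @return Tibble with columns condition, n_trials, and `itpc` (a list column
#'   of per-frequency ITPC vectors).
#' @export
stimulus_itpc <- function(schedule, freqs = NULL, sample_rate = 8000) {
  if (is.null(freqs)) {
    rs <- rate_spec()
    freqs <- c(rs$pair_neighbors[1], rs$pair_rate, rs$pair_neighbors[2],
               rs$element_neighbors[1], rs$element_rate,
               rs$element_neighbors[2])
  }
  trials <- schedule$trials
  ph <- matrix(NA_real_, nrow(trials), length(freqs))
  for (i in seq_len(nrow(trials))) {
    tones <- schedule$tones[schedule$tones$trial_index ==
                              trials$trial_index[i], ]
    wav <- synthesize_audio(tones, sample_rate)
    env <- hilbert_envelope(wav)
    env <- env - mean(env)
    ph[i, ] <- Arg(drop(single_freq_dft(env, sample_rate, freqs)))
  }
  conds <- unique(trials$condition)
  tibble::tibble(
    condition = conds,
    n_trials = vapply(conds, function(cc) sum(trials$condition == cc),
                      integer(1)),
    itpc = lapply(conds, function(cc) {
      sel <- trials$condition == cc
      vapply(seq_along(freqs), function(j) itpc(ph[sel, j]), numeric(1))
    }),
    freqs = list(freqs)
  )
}
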