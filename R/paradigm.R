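#' @importFrom tibble tibble as_tibble
NULL

# Core design constants: 247 ms element onset asynchrony (-> 4.048 Hz element
# rate), 494 ms pair onset asynchrony (-> 2.024 Hz pair rate), 166 ms tones.
SOA_ELEMENT <- 0.247
SOA_PAIR <- 0.494
TONE_DURATION <- 0.166
JITTER_MULTIPLIERS <- c(0.667, 0.834, 1.166, 1.333)
TIMING_CONDITIONS <- c("isochronous", "interval_based", "beat_based")
N_SCALES <- 7L
TONES_PER_SCALE <- 8L
TONES_PER_TRIAL <- N_SCALES * TONES_PER_SCALE

#' Timing condition labels
#' @return Character vector of the three timing conditions.
#' @export
timing_conditions <- function() TIMING_CONDITIONS

#' Jitter set for unpredictable onsets
#'
#' The four inter-onset multipliers (33.3% and 16.6% shorter/longer than the
#' standard 247 ms asynchrony) used to jitter pair-final onsets in the
#' beat-based condition and pair-initial onsets in the interval-based
#' condition.
#' @return Numeric vector of 4 multipliers, symmetric about 1.
#' @export
jitter_multipliers <- function() JITTER_MULTIPLIERS

#' Build one octave scale
#'
#' Eight tone frequencies equally spaced on a logarithmic scale spanning one
#' octave (ratio 2^(1/7) between successive tones), ascending or descending.
#'
#' @param start_f0 Frequency of the first tone in Hz, in \[300, 600\].
#' @param direction `"ascending"` or `"descending"`.
#' @return Numeric vector of 8 frequencies (Hz).
#' @export
#' @examples
#' build_scale(300, "ascending")  # 300 ... 600 Hz
build_scale <- function(start_f0, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (start_f0 < 300 || start_f0 > 600)
    stop("start_f0 must lie in [300, 600] Hz")
  sgn <- if (direction == "ascending") 1 else -1
  start_f0 * 2^(sgn * (0:(TONES_PER_SCALE - 1L)) / (TONES_PER_SCALE - 1L))
}

#' Outlier frequency for a deviant tone
#'
#' A frequency 20% above the maximum or 20% below the minimum of the scale's
#' frequency range; the direction is drawn uniformly at random.
#'
#' @param scale_f0s Frequencies of the scale (Hz).
#' @param direction Optional `"higher"` or `"lower"`; if `NULL` (default) the
#'   direction is drawn at random from the session RNG.
#' @return Outlier frequency in Hz, always outside `range(scale_f0s)`.
#' @export
outlier_f0 <- function(scale_f0s, direction = NULL) {
  if (is.null(direction))
    direction <- sample(c("higher", "lower"), 1L)
  if (direction == "higher") max(scale_f0s) * 1.2 else min(scale_f0s) * 0.8
}

#' Assign tone onsets for one trial
#'
#' Onset times (s from trial start) of the 56 tones under one timing
#' condition:
#' * `isochronous`: fixed 247 ms onset asynchrony throughout.
#' * `beat_based`: pair-initial tones on a fixed 494 ms grid; pair-final
#'   onsets jittered by one draw from the jitter set times 247 ms.
#' * `interval_based`: pair-final onsets fixed 247 ms after their
#'   pair-initial tone; each pair-initial onset shifted from the previous
#'   pair-initial onset + 494 ms by one jitter-set delta (applied to the
#'   actual previous onset, so jitter accumulates).
#'
#' Draws come from the session RNG (seed before calling for reproducibility).
#'
#' @param condition One of [timing_conditions()].
#' @param n_tones Number of tones (default 56).
#' @return Numeric vector of onset times in seconds, strictly increasing.
#' @export
assign_onsets <- function(condition, n_tones = TONES_PER_TRIAL) {
  condition <- match.arg(condition, TIMING_CONDITIONS)
  stopifnot(n_tones %% 2L == 0L)
  n_pairs <- n_tones %/% 2L
  onsets <- numeric(n_tones)
  if (condition == "isochronous") {
    onsets <- (seq_len(n_tones) - 1L) * SOA_ELEMENT
  } else if (condition == "beat_based") {
    pi_on <- (seq_len(n_pairs) - 1L) * SOA_PAIR
    gap <- SOA_ELEMENT * sample(JITTER_MULTIPLIERS, n_pairs, replace = TRUE)
    onsets[2L * seq_len(n_pairs) - 1L] <- pi_on
    onsets[2L * seq_len(n_pairs)] <- pi_on + gap
  } else {
    delta <- SOA_ELEMENT *
      (sample(JITTER_MULTIPLIERS, n_pairs, replace = TRUE) - 1)
    pi_on <- numeric(n_pairs)
    for (p in seq_len(n_pairs)[-1L])
      pi_on[p] <- pi_on[p - 1L] + SOA_PAIR + delta[p]
    onsets[2L * seq_len(n_pairs) - 1L] <- pi_on
    onsets[2L * seq_len(n_pairs)] <- pi_on + SOA_ELEMENT
  }
  onsets
}

# Build the tone table for a single trial (roles still "plain").
new_trial_tones <- function(trial_index, condition, direction, scale_starts) {
  f0 <- unlist(lapply(scale_starts, build_scale, direction = direction))
  position <- rep(0:(TONES_PER_SCALE - 1L), N_SCALES)
  tibble(
    trial_index = trial_index,
    tone = 0:(TONES_PER_TRIAL - 1L),
    scale_index = rep(0:(N_SCALES - 1L), each = TONES_PER_SCALE),
    position = position,
    onset_s = assign_onsets(condition),
    duration_s = TONE_DURATION,
    f0_hz = f0,
    level_db = ifelse(position %% 2L == 1L, -10, 0),
    role = "plain",
    shift_s = 0
  )
}

#' Place the ID and BD deviants in a trial
#'
#' Replaces the final tone of one scale (interval-defining, ID, deviant) and
#' the penultimate tone of a different scale (beat-defining, BD, deviant) with
#' an outlier frequency. Both scales are drawn from scales 2-6 (0-based); the
#' first two scales are always left unaltered.
#'
#' @param tones Trial tone table from the internal builder.
#' @return The tone table with deviant roles and outlier frequencies set;
#'   attribute `deviant_scales` records the two chosen scales (ID, BD).
#' @export
place_deviants <- function(tones) {
  eligible <- 2:6
  if (length(eligible) < 2L) stop("fewer than 2 eligible scales")
  sc <- sample(eligible, 2L)
  for (k in 1:2) {
    pos <- if (k == 1L) 7L else 6L   # ID: scale-final; BD: penultimate
    row <- which(tones$scale_index == sc[k] & tones$position == pos)
    scale_f0s <- tones$f0_hz[tones$scale_index == sc[k]]
    tones$f0_hz[row] <- outlier_f0(scale_f0s)
    tones$role[row] <- if (k == 1L) "deviant_ID" else "deviant_BD"
  }
  attr(tones, "deviant_scales") <- sc
  tones
}

#' Place an immediate tone repetition (behavioral target)
#'
#' In half the trials one unaltered scale among scales 2-6 contains an
#' immediate tone repetition: one tone's frequency is replaced by its
#' predecessor's (the tone count stays 56). The repetition scale is disjoint
#' from the deviant scales.
#'
#' @param tones Trial tone table after [place_deviants()].
#' @param include Whether this trial carries a repetition.
#' @return Updated tone table; attribute `repetition_scale` (or `NA`).
#' @export
place_repetition <- function(tones, include) {
  if (!include) {
    attr(tones, "repetition_scale") <- NA_integer_
    return(tones)
  }
  eligible <- setdiff(2:6, attr(tones, "deviant_scales"))
  if (length(eligible) == 0L) stop("no eligible scale for repetition")
  sc <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  pos <- sample(1:(TONES_PER_SCALE - 1L), 1L)
  row <- which(tones$scale_index == sc & tones$position == pos)
  tones$f0_hz[row] <- tones$f0_hz[row - 1L]
  tones$role[row] <- "repetition"
  attr(tones, "repetition_scale") <- sc
  tones
}

#' Designate standard tones
#'
#' Marks, in two distinct unaltered scales among scales 2-6, the final tone as
#' the designated ID standard and the penultimate tone of the other scale as
#' the designated BD standard. These position-matched standards are the ERP
#' comparison tones for the deviants.
#'
#' @param tones Trial tone table after deviant and repetition placement.
#' @return Updated tone table; attribute `standard_scales` (ID, BD).
#' @export
designate_standards <- function(tones) {
  used <- c(attr(tones, "deviant_scales"), attr(tones, "repetition_scale"))
  eligible <- setdiff(2:6, used[!is.na(used)])
  if (length(eligible) < 2L) stop("insufficient unaltered scales")
  sc <- sample(eligible, 2L)
  for (k in 1:2) {
    pos <- if (k == 1L) 7L else 6L
    row <- which(tones$scale_index == sc[k] & tones$position == pos)
    tones$role[row] <- if (k == 1L) "designated_standard_ID"
                       else "designated_standard_BD"
  }
  attr(tones, "standard_scales") <- sc
  tones
}

#' Fix the onset asynchrony preceding analyzed tones
#'
#' Sets the onset asynchrony between every deviant or designated-standard tone
#' and its immediately preceding tone to exactly 247 ms, so baseline timing is
#' identical across timing conditions. The adjustment is propagated: all later
#' tones in the trial shift by the same amount, keeping the condition's
#' generative rule intact downstream. Column `shift_s` records the cumulative
#' shift applied to each tone.
#'
#' @param tones Trial tone table with roles and onsets assigned.
#' @return Updated tone table.
#' @export
fix_pretarget_isis <- function(tones) {
  targets <- which(tones$role %in% c("deviant_ID", "deviant_BD",
                                     "designated_standard_ID",
                                     "designated_standard_BD"))
  for (j in sort(targets)) {
    new_onset <- tones$onset_s[j - 1L] + SOA_ELEMENT
    delta <- new_onset - tones$onset_s[j]
    idx <- j:nrow(tones)
    tones$onset_s[idx] <- tones$onset_s[idx] + delta
    tones$shift_s[idx] <- tones$shift_s[idx] + delta
  }
  tones
}

# One fully built trial tone table.
build_trial <- function(trial_index, condition, include_repetition) {
  direction <- sample(c("ascending", "descending"), 1L)
  scale_starts <- stats::runif(N_SCALES, 300, 600)
  tones <- new_trial_tones(trial_index, condition, direction, scale_starts)
  tones <- place_deviants(tones)
  tones <- place_repetition(tones, include_repetition)
  tones <- designate_standards(tones)
  tones <- fix_pretarget_isis(tones)
  tones$direction <- direction
  tones
}

# Block condition order: equal counts per condition, no two consecutive
# blocks share a condition. Rejection sampling over random permutations.
block_condition_order <- function(n_blocks) {
  stopifnot(n_blocks %% 3L == 0L)
  base <- rep(TIMING_CONDITIONS, each = n_blocks %/% 3L)
  repeat {
    ord <- sample(base)
    if (all(ord[-1L] != ord[-length(ord)])) return(ord)
  }
}

#' Build a full experiment schedule
#'
#' Deterministically (given the seed) generates the complete experiment plan:
#' blocks of trials in the three timing conditions (no immediate condition
#' repeats), 56-tone scale sequences per trial with one ID and one BD deviant
#' each, repetition decoys in half the trials, designated standards, fixed
#' 247 ms pre-target asynchronies, and a 1 s inter-trial interval.
#'
#' @param seed Integer seed; the schedule is bit-reproducible given the seed.
#' @param n_blocks Number of blocks (multiple of 3; default 12).
#' @param trials_per_block Trials per block (even; default 20).
#' @return An object of class `oddbeat_schedule`: a list with elements
#'   `tones` (one row per tone), `trials`, `blocks`, `iti_s`, and `seed`.
#' @export
#' @examples
#' sched <- build_schedule(1, n_blocks = 3, trials_per_block = 2)
#' nrow(sched$tones)  # 6 trials x 56 tones
build_schedule <- function(seed, n_blocks = 12L, trials_per_block = 20L) {
  stopifnot(trials_per_block %% 2L == 0L)
  set.seed(as.integer(seed))
  n_trials <- n_blocks * trials_per_block
  block_cond <- block_condition_order(n_blocks)
  trial_block <- rep(seq_len(n_blocks), each = trials_per_block)
  trial_cond <- block_cond[trial_block]
  # exactly half the trials in each block carry a repetition decoy
  has_rep <- as.vector(vapply(seq_len(n_blocks), function(b) {
    v <- rep(FALSE, trials_per_block)
    v[sample(trials_per_block, trials_per_block %/% 2L)] <- TRUE
    v
  }, logical(trials_per_block)))

  tone_list <- vector("list", n_trials)
  direction <- character(n_trials)
  for (i in seq_len(n_trials)) {
    tone_list[[i]] <- build_trial(i - 1L, trial_cond[i], has_rep[i])
    direction[i] <- tone_list[[i]]$direction[1L]
  }
  tones <- do.call(rbind, tone_list)
  tones$direction <- NULL
  tones$block <- trial_block[tones$trial_index + 1L]
  tones$condition <- trial_cond[tones$trial_index + 1L]

  # trial start times on the recording timeline: 1 s between last tone offset
  # and the next trial's first tone
  dur <- vapply(tone_list, function(tt)
    max(tt$onset_s) + TONE_DURATION, numeric(1))
  trial_onset <- cumsum(c(0, head_(dur + 1.0, n_trials - 1L)))

  trials <- tibble(
    trial_index = 0:(n_trials - 1L),
    block = trial_block,
    condition = trial_cond,
    direction = direction,
    has_repetition = has_rep,
    trial_onset_s = trial_onset,
    trial_duration_s = dur
  )
  structure(
    list(
      tones = as_tibble(tones),
      trials = trials,
      blocks = tibble(block = seq_len(n_blocks), condition = block_cond),
      iti_s = 1.0,
      seed = as.integer(seed)
    ),
    class = "oddbeat_schedule"
  )
}

head_ <- function(x, n) if (n <= 0L) x[0L] else x[seq_len(n)]

#' @export
print.oddbeat_schedule <- function(x, ...) {
  cat("<oddbeat_schedule> seed", x$seed, "-", nrow(x$trials), "trials,",
      nrow(x$blocks), "blocks,", nrow(x$tones), "tones\n")
  invisible(x)
}

#' Event table of a schedule
#'
#' Flat event table with onsets on the recording timeline, in BIDS-events
#' style (onset and duration in seconds).
#'
#' @param schedule An `oddbeat_schedule`.
#' @return A tibble with columns onset, duration, trial_type, trial_index,
#'   block, condition, scale_index, position, f0_hz, level_db, role.
#' @export
schedule_events <- function(schedule) {
  tn <- schedule$tones
  onset <- tn$onset_s +
    schedule$trials$trial_onset_s[tn$trial_index + 1L]
  tibble(
    onset = onset,
    duration = tn$duration_s,
    trial_type = tn$role,
    trial_index = tn$trial_index,
    block = tn$block,
    condition = tn$condition,
    scale_index = tn$scale_index,
    position = tn$position,
    f0_hz = tn$f0_hz,
    level_db = tn$level_db,
    role = tn$role
  )
}

#' Onset asynchronies between pair-initial tones
#'
#' Differences between onsets of consecutive pair-initial (0-based
#' even-position) tones, per trial, optionally excluding asynchronies altered
#' by the fixed pre-target adjustment (detected via the recorded cumulative
#' shifts).
#'
#' @param schedule An `oddbeat_schedule`.
#' @param condition Timing condition to extract (default `"beat_based"`).
#' @param exclude_adjusted Drop asynchronies whose two endpoint tones carry
#'   different cumulative shifts (default TRUE).
#' @return Numeric vector of onset asynchronies in seconds.
#' @export
pair_onset_asynchronies <- function(schedule, condition = "beat_based",
                                    exclude_adjusted = TRUE) {
  tn <- schedule$tones[schedule$tones$condition == condition &
                         schedule$tones$position %% 2L == 0L, ]
  out <- lapply(split(tn, tn$trial_index), function(tt) {
    d <- diff(tt$onset_s)
    if (exclude_adjusted) d <- d[abs(diff(tt$shift_s)) < 1e-12]
    d
  })
  unlist(out, use.names = FALSE)
}
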