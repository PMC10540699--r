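ERP_CONTENTS <- c("standard", "deviant_ID", "deviant_BD")

#' Condition-wise ERPs for one subject
#'
#' Robust-averages epochs into the Contents x Time cell grid. By default the
#' two designated-standard positions are pooled into a single `standard` cell;
#' with `pool_standards = FALSE` they are kept separate (`standard_ID`,
#' `standard_BD`), as required by the standards-only control analysis.
#'
#' @param epochs An `oddbeat_epochs` object.
#' @param pool_standards Pool the designated-standard positions (default
#'   TRUE).
#' @param lowpass Low-pass applied by the robust average (Hz).
#' @return An `oddbeat_erps` object: `waveforms` array contents x conditions x
#'   channels x time (uV), plus axes metadata.
#' @export
build_condition_erps <- function(epochs, pool_standards = TRUE,
                                 lowpass = 48) {
  conds <- timing_conditions()
  contents <- if (pool_standards) ERP_CONTENTS
              else c("standard_ID", "standard_BD", "deviant_ID", "deviant_BD")
  lab <- epochs$labels$content
  if (pool_standards)
    lab[lab %in% c("standard_ID", "standard_BD")] <- "standard"
  d <- dim(epochs$data)
  w <- array(NA_real_, dim = c(length(contents), length(conds), d[2], d[3]),
             dimnames = list(contents, conds, NULL, NULL))
  for (ci in seq_along(contents)) {
    for (cj in seq_along(conds)) {
      sel <- lab == contents[ci] & epochs$labels$condition == conds[cj]
      if (sum(sel) < 2L)
        stop("cell ", contents[ci], " x ", conds[cj], " has < 2 trials")
      w[ci, cj, , ] <- robust_average(epochs$data[sel, , , drop = FALSE],
                                      fs = epochs$sample_rate_hz,
                                      lowpass = lowpass)
    }
  }
  structure(list(waveforms = w, times = epochs$times,
                 sample_rate_hz = epochs$sample_rate_hz,
                 channels = epochs$channels, montage = epochs$montage,
                 contents = contents, conditions = conds),
            class = "oddbeat_erps")
}

# Stack per-subject ERPs into subjects x contents x conditions x ch x time.
stack_erps <- function(erps_list) {
  d <- dim(erps_list[[1]]$waveforms)
  out <- array(NA_real_, dim = c(length(erps_list), d))
  for (s in seq_along(erps_list)) out[s, , , , ] <- erps_list[[s]]$waveforms
  dimnames(out) <- c(list(NULL), dimnames(erps_list[[1]]$waveforms))
  out
}

#' Spatial smoothing of channel x time maps
#'
#' Applies the Gaussian topography kernel at each time point; the time axis is
#' untouched.
#'
#' @param map Channels x time matrix.
#' @param montage Montage data frame.
#' @param fwhm Kernel FWHM in projection units (default 5).
#' @return Smoothed channels x time matrix.
#' @export
smooth_topo_time <- function(map, montage = standard_montage(), fwhm = 5) {
  smooth_topo(map, montage, fwhm)
}

#' Channel-by-time repeated-measures ANOVA maps
#'
#' Smooths each subject's cell maps spatially, then computes per channel-time
#' point the within-subject F maps of a 3 x 3 repeated-measures ANOVA with
#' factors Contents (standard, deviant ID, deviant BD) and Time (isochronous,
#' interval-based, beat-based).
#'
#' @param erps_list List of per-subject `oddbeat_erps` (pooled standards).
#' @param fwhm Spatial smoothing FWHM (0 to skip).
#' @return List with `contents`, `time`, `interaction` (each: `F` channels x
#'   time matrix, `df`, `p`) plus axes metadata.
#' @export
anova_map <- function(erps_list, fwhm = 5) {
  y <- stack_erps(erps_list)
  if (dim(y)[2] != 3L) stop("expected 3 pooled content levels")
  mont <- erps_list[[1]]$montage
  n <- dim(y)[1]; n_ch <- dim(y)[4]; n_t <- dim(y)[5]
  if (fwhm > 0) {
    for (s in seq_len(n)) for (i in 1:3) for (j in 1:3)
      y[s, i, j, , ] <- smooth_topo(y[s, i, j, , ], mont, fwhm)
  }
  yy <- array(y, dim = c(n, 3, 3, n_ch * n_t))
  res <- rm_anova_twoway(yy)
  shape <- function(r) list(F = matrix(r$F, n_ch, n_t), df = r$df,
                            p = matrix(r$p, n_ch, n_t))
  list(contents = shape(res$A), time = shape(res$B),
       interaction = shape(res$AB),
       times = erps_list[[1]]$times, channels = erps_list[[1]]$channels)
}

# Per-subject channel x time contrast maps for a named contrast.
subject_contrast_maps <- function(erps_list, contrast = c("congruence",
                                                          "mismatch",
                                                          "standards_control"),
                                  fwhm = 5) {
  contrast <- match.arg(contrast)
  y <- stack_erps(erps_list)
  cn <- dimnames(y)[[2]]
  n <- dim(y)[1]; n_ch <- dim(y)[4]; n_t <- dim(y)[5]
  maps <- array(NA_real_, dim = c(n, n_ch, n_t))
  for (s in seq_len(n)) {
    m <- switch(contrast,
      congruence =
        y[s, "deviant_ID", "interval_based", , ] -
        y[s, "deviant_ID", "beat_based", , ] -
        y[s, "deviant_BD", "interval_based", , ] +
        y[s, "deviant_BD", "beat_based", , ],
      mismatch =
        (y[s, "deviant_ID", , , ] + y[s, "deviant_BD", , , ]) / 2 -
        y[s, "standard", , , ],
      standards_control =
        y[s, "standard_ID", "interval_based", , ] -
        y[s, "standard_ID", "beat_based", , ] -
        y[s, "standard_BD", "interval_based", , ] +
        y[s, "standard_BD", "beat_based", , ]
    )
    if (contrast == "mismatch") m <- apply(m, c(2, 3), mean)  # pool Time
    maps[s, , ] <- if (fwhm > 0)
      smooth_topo(m, erps_list[[s]]$montage, fwhm) else m
  }
  maps
}

#' Planned congruence (2 x 2 interaction) contrast
#'
#' Per subject, the interaction of Contents (deviant ID, deviant BD) and Time
#' (interval-based, beat-based) with weights (+1, -1, -1, +1); across
#' subjects, a one-sample t (reported also as F = t^2) per channel-time point.
#' Exactly zero whenever the four cell means are additive.
#'
#' @param erps_list List of per-subject `oddbeat_erps`.
#' @param fwhm Spatial smoothing FWHM.
#' @return List with `t`, `F` (channels x time), `df`, and the per-subject
#'   `maps`.
#' @export
congruence_contrast <- function(erps_list, fwhm = 5) {
  maps <- subject_contrast_maps(erps_list, "congruence", fwhm)
  one_sample_stat(maps)
}

#' Deviant-versus-standard (mismatch) contrast
#'
#' Per subject, the mean deviant ERP (both types) minus the standard ERP,
#' pooled over timing conditions; across subjects a one-sample t / F map.
#'
#' @inheritParams congruence_contrast
#' @return As [congruence_contrast()].
#' @export
mismatch_contrast <- function(erps_list, fwhm = 5) {
  maps <- subject_contrast_maps(erps_list, "mismatch", fwhm)
  one_sample_stat(maps)
}

one_sample_stat <- function(maps) {
  n <- dim(maps)[1]
  m <- matrix(maps, n, prod(dim(maps)[2:3]))
  mu <- colMeans(m)
  va <- (colSums(m^2) - n * mu^2) / (n - 1)
  tval <- mu / sqrt(pmax(va, .Machine$double.xmin) / n)
  tval[va < 1e-300 & abs(mu) < 1e-300] <- 0
  list(t = matrix(tval, dim(maps)[2], dim(maps)[3]),
       F = matrix(tval^2, dim(maps)[2], dim(maps)[3]),
       df = c(1L, n - 1L), maps = maps)
}

#' Cluster-level permutation inference for a one-sample contrast
#'
#' Thresholds the F = t^2 map at the cluster-forming p (two-sided on t),
#' groups suprathreshold points into clusters by spatial adjacency and
#' temporal contiguity, and calibrates familywise cluster p-values against the
#' maximum cluster mass over random subject sign flips.
#'
#' @param contrast Output of [congruence_contrast()] or [mismatch_contrast()].
#' @param montage Montage data frame.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param forming_p Cluster-forming threshold (default 0.001).
#' @param seed RNG seed for the sign flips.
#' @return An `oddbeat_clusters` object (masses on the F scale).
#' @export
cluster_inference <- function(contrast, montage = standard_montage(),
                              n_perm = 200L, forming_p = 0.001, seed = 1) {
  maps <- contrast$maps
  n <- dim(maps)[1]
  thr <- stats::qf(1 - forming_p, 1, n - 1L)
  adj <- channel_adjacency(montage)
  m <- matrix(maps, n, prod(dim(maps)[2:3]))
  ssq <- colSums(m^2)
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
  perm_fun <- function(i) {
    mu <- drop(signs[i, ] %*% m) / n
    va <- (ssq - n * mu^2) / (n - 1)
    tval <- mu / sqrt(pmax(va, .Machine$double.xmin) / n)
    matrix(tval^2, dim(maps)[2], dim(maps)[3])
  }
  cluster_inference_generic(contrast$F, thr, adj, perm_fun, n_perm)
}

#' Post-hoc pairwise comparisons
#'
#' Paired t-tests on cluster-averaged values for all pairs of conditions, with
#' Bonferroni correction over the stated number of comparisons.
#'
#' @param values Subjects x conditions matrix (e.g. cluster-averaged
#'   amplitudes or ITPC).
#' @param labels Condition labels (column names).
#' @param n_comparisons Bonferroni factor (default: number of pairs).
#' @return Tibble with one row per pair: t, df, p, p_bonf.
#' @export
posthoc_pairwise <- function(values, labels = colnames(values),
                             n_comparisons = NULL) {
  k <- ncol(values)
  prs <- utils::combn(k, 2)
  if (is.null(n_comparisons)) n_comparisons <- ncol(prs)
  out <- vector("list", ncol(prs))
  for (j in seq_len(ncol(prs))) {
    i1 <- prs[1, j]; i2 <- prs[2, j]
    d <- values[, i1] - values[, i2]
    if (stats::sd(d) < 1e-12) {
      # degenerate: constant difference across subjects
      tt <- if (abs(mean(d)) < 1e-12)
        list(statistic = c(t = 0), parameter = c(df = nrow(values) - 1),
             p.value = 1)
      else
        list(statistic = c(t = sign(mean(d)) * Inf),
             parameter = c(df = nrow(values) - 1), p.value = 0)
    } else tt <- stats::t.test(d)
    out[[j]] <- tibble::tibble(a = labels[i1], b = labels[i2],
                               t = unname(tt$statistic),
                               df = unname(tt$parameter), p = tt$p.value)
  }
  res <- do.call(rbind, out)
  res$p_bonf <- pmin(res$p * n_comparisons, 1)
  res
}

#' Standards-only control analysis
#'
#' Applies the 2 x 2 congruence machinery to the designated standards (split
#' by position type) instead of the deviants. With a deviant-specific
#' congruence effect this control yields no significant clusters.
#'
#' @param erps_list Per-subject `oddbeat_erps` built with
#'   `pool_standards = FALSE`.
#' @param montage,n_perm,forming_p,seed Passed to [cluster_inference()].
#' @param fwhm Spatial smoothing FWHM.
#' @return An `oddbeat_clusters` object.
#' @export
standards_control <- function(erps_list, montage = standard_montage(),
                              n_perm = 200L, forming_p = 0.001, fwhm = 5,
                              seed = 1) {
  if (!all(c("standard_ID", "standard_BD") %in% erps_list[[1]]$contents))
    stop("standards not separable: build ERPs with pool_standards = FALSE")
  maps <- subject_contrast_maps(erps_list, "standards_control", fwhm)
  cluster_inference(one_sample_stat(maps), montage, n_perm, forming_p, seed)
}

#' Union mask of significant clusters
#'
#' @param cluster_result An `oddbeat_clusters` object.
#' @param alpha Familywise threshold (default 0.05).
#' @param fallback_nodes Node indices to use when no cluster is significant
#'   (NULL to return an empty mask).
#' @return Integer node indices into the channels x time stat map.
#' @export
cluster_mask <- function(cluster_result, alpha = 0.05,
                         fallback_nodes = NULL) {
  sig <- Filter(function(cl) cl$p_fwe < alpha, cluster_result$clusters)
  if (length(sig) == 0L) return(as.integer(fallback_nodes))
  sort(unique(unlist(lapply(sig, `[[`, "nodes"))))
}

#' Per-subject mismatch and congruence indices
#'
#' The mismatch index is the difference between the absolute deviant-evoked
#' and absolute standard-evoked amplitudes (pooled over deviant types and
#' timing conditions), averaged over the mismatch cluster mask. The congruence
#' index is the congruent-deviant amplitude (ID x interval-based plus BD x
#' beat-based) minus the incongruent one, averaged over the interaction
#' cluster mask.
#'
#' @param erps_list Per-subject `oddbeat_erps` (pooled standards).
#' @param mismatch_mask,congruence_mask Node indices into the channels x time
#'   grid (from [cluster_mask()]).
#' @return Tibble with one row per subject: `mismatch_index`,
#'   `congruence_index` (uV).
#' @export
subject_indices <- function(erps_list, mismatch_mask, congruence_mask) {
  if (length(mismatch_mask) == 0L || length(congruence_mask) == 0L)
    stop("empty cluster mask")
  y <- stack_erps(erps_list)
  n <- dim(y)[1]
  mm <- numeric(n); cg <- numeric(n)
  for (s in seq_len(n)) {
    dev <- (apply(y[s, "deviant_ID", , , ], c(2, 3), mean) +
              apply(y[s, "deviant_BD", , , ], c(2, 3), mean)) / 2
    std <- apply(y[s, "standard", , , ], c(2, 3), mean)
    mm[s] <- mean(abs(dev[mismatch_mask])) - mean(abs(std[mismatch_mask]))
    congr <- (y[s, "deviant_ID", "interval_based", , ] +
                y[s, "deviant_BD", "beat_based", , ]) / 2
    incon <- (y[s, "deviant_ID", "beat_based", , ] +
                y[s, "deviant_BD", "interval_based", , ]) / 2
    cg[s] <- mean(congr[congruence_mask]) - mean(incon[congruence_mask])
  }
  tibble::tibble(subject = seq_len(n), mismatch_index = mm,
                 congruence_index = cg)
}
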