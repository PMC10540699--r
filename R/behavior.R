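#' Score the repetition-detection task
#'
#' A hit is a response within (0, 2\] s of the repetition tone; reaction times
#' longer than 2 s are excluded from analysis (and do not count as hits).
#' Accuracy is the percentage of repetition trials with a hit; the mean RT
#' (correct trials only) is log-transformed.
#'
#' @param responses Response tibble (`subject`, `condition`, `half`, `hit`,
#'   `rt_s`), e.g. from [synth_behavior()], possibly row-bound over subjects.
#' @param rt_max RT exclusion bound in seconds (default 2).
#' @param by_half Also split by experiment half.
#' @return Tibble per subject x condition (x half): `n_trials`, `accuracy`
#'   (%), `mean_rt_s`, `log_rt` (log seconds; NA when no correct trial, with
#'   a message).
#' @export
score_and_filter <- function(responses, rt_max = 2, by_half = FALSE) {
  keys <- c("subject", "condition", if (by_half) "half")
  grp <- interaction(responses[keys], drop = TRUE)
  out <- lapply(split(responses, grp), function(d) {
    valid_hit <- d$hit & !is.na(d$rt_s) & d$rt_s <= rt_max & d$rt_s > 0
    mean_rt <- if (any(valid_hit)) mean(d$rt_s[valid_hit]) else NA_real_
    cbind(d[1L, keys, drop = FALSE],
          tibble::tibble(n_trials = nrow(d),
                         accuracy = 100 * mean(valid_hit),
                         mean_rt_s = mean_rt,
                         log_rt = log(mean_rt)))
  })
  res <- tibble::as_tibble(do.call(rbind, out))
  if (anyNA(res$log_rt))
    message("subject(s) with zero correct trials in a condition: log_rt NA")
  rownames(res) <- NULL
  res
}

#' Repeated-measures ANOVA over timing conditions
#'
#' One-way within-subject ANOVA of a per-subject, per-condition measure
#' (accuracy or log RT), with FDR-corrected paired t post-hocs over the three
#' pairwise comparisons.
#'
#' @param values Subjects x 3 matrix, columns in [timing_conditions()] order
#'   (complete cases required).
#' @return List with `F`, `df`, `p`, and `posthoc` (tibble with `p_fdr`).
#' @export
rm_anova_time <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells; complete cases required")
  if (ncol(values) != 3L) stop("expected 3 conditions")
  r <- rm_anova_oneway(values)
  ph <- posthoc_pairwise(values, labels = timing_conditions())
  ph$p_bonf <- NULL
  ph$p_fdr <- stats::p.adjust(ph$p, method = "BH")
  list(F = r$F, df = r$df, p = r$p, posthoc = ph)
}

#' Wilcoxon signed-rank tests between experiment halves
#'
#' For each condition, paired signed-rank tests of accuracy and of mean RT
#' between the first and second experiment halves, across subjects. Zero
#' differences are dropped (with `p = 1` when none remain); the exact
#' distribution is used for n <= 25 without ties.
#'
#' @param scored Output of `score_and_filter(..., by_half = TRUE)`.
#' @return Tibble per condition x measure: `statistic` (V), `p`.
#' @export
halves_tests <- function(scored) {
  out <- list()
  for (cond in unique(scored$condition)) {
    for (measure in c("accuracy", "mean_rt_s")) {
      d <- scored[scored$condition == cond, ]
      wide <- stats::reshape(as.data.frame(
        d[, c("subject", "half", measure)]),
        idvar = "subject", timevar = "half", direction = "wide")
      x <- wide[[paste0(measure, ".second")]]
      y <- wide[[paste0(measure, ".first")]]
      ok <- stats::complete.cases(x, y)
      diffs <- x[ok] - y[ok]
      if (all(diffs == 0)) {
        res <- list(statistic = c(V = 0), p.value = 1)
        message("all-zero differences for ", cond, "/", measure, "; p = 1")
      } else {
        res <- suppressWarnings(
          stats::wilcox.test(x[ok], y[ok], paired = TRUE,
                             exact = sum(diffs != 0) <= 25))
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = cond, measure = measure,
        statistic = unname(res$statistic), p = res$p.value, n = sum(ok))
    }
  }
  do.call(rbind, out)
}

#' Brain-behavior regression and correlation report
#'
#' Regresses the behavioral accuracy index on the three neural indices,
#' excludes subjects whose Cook's distance exceeds 5 times the mean Cook's
#' distance, then reports Pearson correlations among all measure pairs on the
#' remaining subjects with Bonferroni correction over the tested pairs.
#'
#' @param indices Tibble with columns `behavioral_index`, `itpc_index`,
#'   `congruence_index`, `mismatch_index` (one row per subject).
#' @param cook_factor Exclusion multiplier on the mean Cook's distance
#'   (default 5).
#' @return List with `model` (the post-exclusion lm fit), `excluded` (row
#'   indices), `correlations` (tibble: pair, r, p, p_bonf, n).
#' @export
brain_behavior <- function(indices, cook_factor = 5) {
  vars <- c("behavioral_index", "itpc_index", "congruence_index",
            "mismatch_index")
  stopifnot(all(vars %in% names(indices)))
  dat <- as.data.frame(indices[, vars])
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 5L) stop("need >= 5 complete rows")
  fit <- stats::lm(behavioral_index ~ itpc_index + congruence_index +
                     mismatch_index, data = dat)
  cd <- stats::cooks.distance(fit)
  excluded <- which(cd > cook_factor * mean(cd))
  kept <- if (length(excluded)) dat[-excluded, ] else dat
  fit2 <- stats::lm(behavioral_index ~ itpc_index + congruence_index +
                      mismatch_index, data = kept)
  prs <- utils::combn(vars, 2)
  cors <- lapply(seq_len(ncol(prs)), function(j) {
    ct <- stats::cor.test(kept[[prs[1, j]]], kept[[prs[2, j]]])
    tibble::tibble(a = prs[1, j], b = prs[2, j],
                   r = unname(ct$estimate), p = ct$p.value, n = nrow(kept))
  })
  cors <- do.call(rbind, cors)
  cors$p_bonf <- pmin(cors$p * nrow(cors), 1)
  list(model = fit2, excluded = as.integer(excluded), correlations = cors)
}

#' Simulate subject-level brain-behavior indices
#'
#' Index-level generator for correlation-recovery studies: the congruence and
#' ITPC indices are drawn from a bivariate normal with correlation `r`; the
#' behavioral and mismatch indices are independent noise on realistic scales.
#'
#' @param n Number of subjects.
#' @param r Generative correlation between the congruence and ITPC indices.
#' @param seed Integer seed.
#' @return Tibble with the four index columns.
#' @export
synth_subject_indices <- function(n, r = 0.65, seed = 1) {
  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  tibble::tibble(
    subject = seq_len(n),
    behavioral_index = stats::rnorm(n, 5.2, 4),     # accuracy difference, %
    itpc_index = -1.5 + 1.0 * z1,                   # pair-rate ITPC diff
    congruence_index = -0.17 + 0.35 * z2,           # uV
    mismatch_index = stats::rnorm(n, -0.2, 0.3)     # uV
  )
}
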