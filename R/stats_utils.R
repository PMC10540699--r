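# Vectorized within-subject (repeated-measures) ANOVA machinery shared by the
# spectral, ERP, and behavioral analyses.

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test for a single factor, computed from cell values with
#' subject as blocking factor. Vectorized over any number of response units
#' (e.g. channels or channel-time points).
#'
#' @param y Matrix subjects x conditions, or 3-d array subjects x conditions x
#'   units.
#' @return List with `F` (scalar or vector over units), `df` (numerator,
#'   denominator), and `p`.
#' @export
rm_anova_oneway <- function(y) {
  if (length(dim(y)) == 2L) y <- array(y, dim = c(dim(y), 1L))
  n <- dim(y)[1]; k <- dim(y)[2]; m <- dim(y)[3]
  if (n < 2L) stop("need >= 2 subjects")
  grand <- apply(y, 3, mean)
  cond_m <- apply(y, c(2, 3), mean)           # k x m
  subj_m <- apply(y, c(1, 3), mean)           # n x m
  ss_cond <- n * colSums((cond_m - rep(grand, each = k))^2)
  resid <- y - aperm(array(cond_m, dim = c(k, m, n)), c(3, 1, 2)) -
    aperm(array(subj_m, dim = c(n, m, k)), c(1, 3, 2)) +
    aperm(array(grand, dim = c(m, n, k)), c(2, 3, 1))
  ss_err <- apply(resid^2, 3, sum)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  f <- (ss_cond / df1) / pmax(ss_err / df2, .Machine$double.xmin)
  # sums of squares at rounding level relative to the data are treated as 0
  tol <- 1e-20 * apply(y, 3, function(v) sum((v - mean(v))^2)) + 1e-300
  f[ss_cond < tol & ss_err < tol] <- 0
  list(F = drop(f), df = c(df1, df2), p = drop(stats::pf(f, df1, df2,
                                                         lower.tail = FALSE)))
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject F tests for two crossed factors and their interaction, one
#' observation (cell mean) per subject and cell, vectorized over units. Each
#' effect is tested against its own subject-by-effect interaction error term.
#'
#' @param y 4-d array subjects x levels(A) x levels(B) x units (the last
#'   dimension may be dropped).
#' @return List of three lists (`A`, `B`, `AB`), each with `F`, `df`, `p`.
#' @export
rm_anova_twoway <- function(y) {
  if (length(dim(y)) == 3L) y <- array(y, dim = c(dim(y), 1L))
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]; m <- dim(y)[4]
  if (n < 2L) stop("need >= 2 subjects")
  ym <- matrix(y, n * a * b, m)
  idx <- expand.grid(s = seq_len(n), i = seq_len(a), j = seq_len(b))
  mean_by <- function(g) {
    gm <- rowsum(ym, g) / as.vector(table(g))
    gm
  }
  grand <- colMeans(ym)
  m_a <- mean_by(idx$i)                        # a x m
  m_b <- mean_by(idx$j)                        # b x m
  m_s <- mean_by(idx$s)                        # n x m
  m_ab <- mean_by(interaction(idx$i, idx$j))   # (a*b) x m
  m_as <- mean_by(interaction(idx$s, idx$i))   # (n*a) x m
  m_bs <- mean_by(interaction(idx$s, idx$j))   # (n*b) x m

  center <- function(x) sweep(x, 2, grand)
  ss <- function(x) colSums(x^2)
  ss_a <- n * b * ss(center(m_a))
  ss_b <- n * a * ss(center(m_b))
  g_ab <- expand.grid(i = seq_len(a), j = seq_len(b))
  ss_ab <- n * ss(m_ab - m_a[g_ab$i, , drop = FALSE] -
                    m_b[g_ab$j, , drop = FALSE] +
                    rep(grand, each = a * b))
  g_as <- expand.grid(s = seq_len(n), i = seq_len(a))
  ss_as <- b * ss(m_as - m_a[g_as$i, , drop = FALSE] -
                    m_s[g_as$s, , drop = FALSE] + rep(grand, each = n * a))
  g_bs <- expand.grid(s = seq_len(n), j = seq_len(b))
  ss_bs <- a * ss(m_bs - m_b[g_bs$j, , drop = FALSE] -
                    m_s[g_bs$s, , drop = FALSE] + rep(grand, each = n * b))
  # three-way residual for the interaction error term
  key_ab <- (idx$j - 1L) * a + idx$i
  key_as <- (idx$i - 1L) * n + idx$s
  key_bs <- (idx$j - 1L) * n + idx$s
  fitted <- m_ab[key_ab, , drop = FALSE] + m_as[key_as, , drop = FALSE] +
    m_bs[key_bs, , drop = FALSE] - m_a[idx$i, , drop = FALSE] -
    m_b[idx$j, , drop = FALSE] - m_s[idx$s, , drop = FALSE] +
    rep(grand, each = n * a * b)
  ss_abs <- colSums((ym - fitted)^2)

  # sums of squares at rounding level relative to the data are treated as 0
  tol <- 1e-20 * colSums(sweep(ym, 2, grand)^2) + 1e-300
  mk <- function(sse, df1, sserr, df2) {
    f <- (sse / df1) / pmax(sserr / df2, .Machine$double.xmin)
    f[sse < tol & sserr < tol] <- 0
    list(F = drop(f), df = c(df1, df2),
         p = drop(stats::pf(f, df1, df2, lower.tail = FALSE)))
  }
  list(
    A = mk(ss_a, a - 1L, ss_as, (a - 1L) * (n - 1L)),
    B = mk(ss_b, b - 1L, ss_bs, (b - 1L) * (n - 1L)),
    AB = mk(ss_ab, (a - 1L) * (b - 1L), ss_abs,
            (a - 1L) * (b - 1L) * (n - 1L))
  )
}

# Connected suprathreshold clusters of a channel(-by-time) statistic map.
# stat: channels x time matrix (or vector over channels); adjacency: logical
# channel adjacency matrix. Returns list of clusters (node indices into the
# stat array) with their mass (sum of the statistic over the cluster).
find_clusters <- function(stat, threshold, adjacency) {
  stat <- as.matrix(stat)
  n_ch <- nrow(stat); n_t <- ncol(stat)
  supra <- which(stat > threshold)
  if (length(supra) == 0L)
    return(list())
  node_id <- integer(n_ch * n_t)
  node_id[supra] <- seq_along(supra)
  edges <- NULL
  ch_of <- (supra - 1L) %% n_ch + 1L
  t_of <- (supra - 1L) %/% n_ch + 1L
  # temporal neighbors: same channel, next time point
  nxt <- supra + n_ch
  ok <- t_of < n_t & nxt %in% supra
  if (any(ok)) edges <- cbind(node_id[supra[ok]], node_id[nxt[ok]])
  # spatial neighbors: adjacent channels, same time point
  adj_idx <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  if (nrow(adj_idx) > 0L) {
    for (tt in unique(t_of)) {
      off <- (tt - 1L) * n_ch
      here <- node_id[off + seq_len(n_ch)]
      a <- here[adj_idx[, 1L]]
      b <- here[adj_idx[, 2L]]
      ok <- a > 0L & b > 0L
      if (any(ok)) edges <- rbind(edges, cbind(a[ok], b[ok]))
    }
  }
  g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lapply(split(seq_along(supra), comp), function(ix) {
    nodes <- supra[ix]
    list(nodes = nodes,
         channels = unique((nodes - 1L) %% n_ch + 1L),
         times = unique((nodes - 1L) %/% n_ch + 1L),
         mass = sum(stat[nodes]))
  })
}

# Familywise-corrected cluster inference from an observed statistic map and a
# generator of permutation statistic maps (same shape). The null distribution
# is the maximum suprathreshold cluster mass per permutation.
cluster_inference_generic <- function(stat_obs, threshold, adjacency,
                                      perm_fun, n_perm) {
  if (n_perm < 100L) stop("need >= 100 permutations")
  clusters <- find_clusters(stat_obs, threshold, adjacency)
  null_max <- vapply(seq_len(n_perm), function(i) {
    cl <- find_clusters(perm_fun(i), threshold, adjacency)
    if (length(cl) == 0L) 0 else max(vapply(cl, `[[`, numeric(1), "mass"))
  }, numeric(1))
  for (k in seq_along(clusters))
    clusters[[k]]$p_fwe <- (1 + sum(null_max >= clusters[[k]]$mass)) /
      (1 + n_perm)
  structure(list(clusters = clusters, threshold = threshold,
                 null_max = null_max, n_perm = n_perm),
            class = "oddbeat_clusters")
}

#' @export
print.oddbeat_clusters <- function(x, ...) {
  cat("<oddbeat_clusters>", length(x$clusters), "suprathreshold clusters (",
      x$n_perm, "permutations )\n")
  for (cl in x$clusters)
    cat(sprintf("  mass %.2f, %d channels, %d time points, p_fwe = %.4f\n",
                cl$mass, length(cl$channels), length(cl$times), cl$p_fwe))
  invisible(x)
}

#' Smallest familywise cluster p-value
#'
#' Convenience accessor: the minimum `p_fwe` over all clusters of an
#' `oddbeat_clusters` result, or 1 when there is no suprathreshold cluster.
#'
#' @param res An `oddbeat_clusters` object.
#' @return A single p-value.
#' @export
min_cluster_p <- function(res) {
  if (length(res$clusters) == 0L) return(1)
  min(vapply(res$clusters, `[[`, numeric(1), "p_fwe"))
}
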