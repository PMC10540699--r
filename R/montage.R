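#' Standard 64-channel scalp montage
#'
#' Builds the 64-channel 10-10 montage used throughout the package, with 2-D
#' projected coordinates on the scalp-image scale (units chosen so that the
#' nearest-neighbor inter-electrode distance is 5 units, matching the 5-unit
#' FWHM of the topography smoothing kernel).
#'
#' @return A data frame with columns `name`, `x`, `y` (projected coordinates)
#'   and `mirror` (the left-right mirror channel; midline channels map to
#'   themselves).
#' @export
#' @examples
#' m <- standard_montage()
#' nrow(m)  # 64
standard_montage <- function() {
  rows <- list(
    list(y =  4, chans = c(Fp1 = -1, Fpz = 0, Fp2 = 1)),
    list(y =  3, chans = c(AF7 = -4, AF3 = -2, AFz = 0, AF4 = 2, AF8 = 4)),
    list(y =  2, chans = c(F7 = -4, F5 = -3, F3 = -2, F1 = -1, Fz = 0,
                           F2 = 1, F4 = 2, F6 = 3, F8 = 4)),
    list(y =  1, chans = c(FT7 = -4, FC5 = -3, FC3 = -2, FC1 = -1, FCz = 0,
                           FC2 = 1, FC4 = 2, FC6 = 3, FT8 = 4)),
    list(y =  0, chans = c(T7 = -4, C5 = -3, C3 = -2, C1 = -1, Cz = 0,
                           C2 = 1, C4 = 2, C6 = 3, T8 = 4)),
    list(y = -1, chans = c(TP7 = -4, CP5 = -3, CP3 = -2, CP1 = -1, CPz = 0,
                           CP2 = 1, CP4 = 2, CP6 = 3, TP8 = 4)),
    list(y = -2, chans = c(P9 = -5, P7 = -4, P5 = -3, P3 = -2, P1 = -1,
                           Pz = 0, P2 = 1, P4 = 2, P6 = 3, P8 = 4, P10 = 5)),
    list(y = -3, chans = c(PO7 = -4, PO3 = -2, POz = 0, PO4 = 2, PO8 = 4)),
    list(y = -4, chans = c(O1 = -1, Oz = 0, O2 = 1)),
    list(y = -5, chans = c(Iz = 0))
  )
  name <- unlist(lapply(rows, function(r) names(r$chans)), use.names = FALSE)
  x <- unlist(lapply(rows, function(r) unname(r$chans)), use.names = FALSE)
  y <- unlist(lapply(rows, function(r) rep(r$y, length(r$chans))),
              use.names = FALSE)
  # grid spacing of 5 projection units
  out <- data.frame(name = name, x = 5 * x, y = 5 * y,
                    stringsAsFactors = FALSE)
  out$mirror <- vapply(out$name, mirror_channel_name, character(1))
  stopifnot(nrow(out) == 64L, all(out$mirror %in% out$name))
  out
}

# Left-right mirror of a 10-10 channel name: odd terminal digits are left,
# even are right; 'z' (and Iz) channels are midline and map to themselves.
mirror_channel_name <- function(name) {
  m <- regmatches(name, regexpr("[0-9]+$", name))
  if (length(m) == 0L) return(name)            # ends in 'z'
  n <- as.integer(m)
  prefix <- sub("[0-9]+$", "", name)
  paste0(prefix, if (n %% 2L == 1L) n + 1L else n - 1L)
}

#' Channel adjacency from projected positions
#'
#' Two channels are neighbors when their projected distance does not exceed
#' `factor` times the median nearest-neighbor distance of the montage. On the
#' regular montage grid this links lateral, anterior-posterior, and diagonal
#' neighbors.
#'
#' @param montage Data frame as returned by [standard_montage()].
#' @param factor Distance multiplier applied to the median nearest-neighbor
#'   distance (default 1.5).
#' @return A logical `n x n` adjacency matrix (diagonal `FALSE`), with channel
#'   names as dimnames.
#' @export
channel_adjacency <- function(montage, factor = 1.5) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  dimnames(d) <- list(montage$name, montage$name)
  nn <- apply(d + diag(Inf, nrow(d)), 1, min)
  adj <- d <= factor * stats::median(nn) & d > 0
  adj
}

#' Swap left and right channels of a topography map
#'
#' Exchanges values between mirror-paired channels (e.g. C3 and C4); midline
#' channels are unchanged. Used as a handedness control for lateralized
#' topographies.
#'
#' @param values Named numeric vector (names must be montage channel names),
#'   or a matrix with one row per channel.
#' @param montage Montage data frame (default [standard_montage()]).
#' @return The flipped values, same shape as the input.
#' @export
flip_lr <- function(values, montage = standard_montage()) {
  if (is.matrix(values)) {
    nm <- rownames(values)
    if (is.null(nm)) stop("matrix input must have channel rownames")
    idx <- match(montage$mirror[match(nm, montage$name)], nm)
    if (anyNA(idx)) stop("unpaired lateral channel in input")
    out <- values[idx, , drop = FALSE]
    rownames(out) <- nm
    return(out)
  }
  nm <- names(values)
  if (is.null(nm)) stop("values must be named by channel")
  idx <- match(montage$mirror[match(nm, montage$name)], nm)
  if (anyNA(idx)) stop("unpaired lateral channel in input")
  out <- values[idx]
  names(out) <- nm
  out
}

#' Spatial Gaussian smoothing of topographies
#'
#' Smooths channel-wise values with a Gaussian kernel over projected
#' inter-channel distances. The kernel is balanced to doubly stochastic form
#' (Sinkhorn normalization), so the total mass of the map is conserved and
#' constant maps pass through unchanged. The time axis (matrix columns) is
#' not smoothed.
#'
#' @param values Numeric vector (one value per channel) or channels-by-time
#'   matrix, ordered as `montage$name`.
#' @param montage Montage data frame.
#' @param fwhm Full width at half maximum of the kernel in projection units
#'   (default 5, the nearest-neighbor spacing).
#' @return Smoothed values, same shape as input.
#' @export
smooth_topo <- function(values, montage = standard_montage(), fwhm = 5) {
  if (fwhm <= 0) return(values)
  k <- smoothing_kernel(montage, fwhm)
  if (is.matrix(values)) {
    out <- k %*% values
    dimnames(out) <- dimnames(values)
    out
  } else {
    out <- drop(k %*% values)
    names(out) <- names(values)
    out
  }
}

# Doubly stochastic Gaussian smoothing kernel (cached per montage size/fwhm).
smoothing_kernel <- local({
  cache <- new.env(parent = emptyenv())
  function(montage, fwhm) {
    key <- paste0(nrow(montage), "_", fwhm, "_",
                  signif(sum(montage$x^2 + montage$y^2), 10))
    if (!is.null(cache[[key]])) return(cache[[key]])
    d <- as.matrix(stats::dist(montage[, c("x", "y")]))
    k <- exp(-4 * log(2) * (d / fwhm)^2)
    for (i in 1:500) {                 # Sinkhorn balancing (symmetric)
      k <- k / rowSums(k)
      k <- (k + t(k)) / 2
      if (max(abs(rowSums(k) - 1)) < 1e-13) break
    }
    cache[[key]] <- k
    k
  }
})
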