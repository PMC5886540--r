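#' Parameters for circular binary segmentation
#'
#' @param alpha Significance level for declaring a change (default 0.01).
#' @param n_perm Number of permutations calibrating the split test
#'   (default 10000; at least 100).
#' @param min_width Minimum number of bins per segment (default 2).
#' @param seed RNG seed used by [segment_cbs()] (default 42).
#' @return A `cbs_params` list.
#' @export
cbs_params <- function(alpha = 0.01, n_perm = 10000, min_width = 2, seed = 42) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_width >= 1)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), seed = as.integer(seed)),
            class = "cbs_params")
}

#' Circular-interval t-statistic
#'
#' `T = (mean(arc) - mean(complement)) / sqrt(1/k + 1/(n - k))` for the arc
#' of bins `i..j` (1-based inclusive; `j < i` wraps around the end). The
#' sign is retained; the complement must be non-empty.
#'
#' @param x Depth vector.
#' @param i,j Arc endpoints (1-based, inclusive; `j < i` denotes a wrapped
#'   arc).
#' @return The signed statistic.
#' @export
cbs_t_statistic <- function(x, i, j) {
  n <- length(x)
  stopifnot(i >= 1, i <= n, j >= 1, j <= n)
  idx <- if (j >= i) i:j else c(i:n, 1:j)
  k <- length(idx)
  if (k >= n) stop("arc must leave a non-empty complement")
  mu <- mean(x[idx])
  mu_bar <- (sum(x) - sum(x[idx])) / (n - k)
  (mu - mu_bar) / sqrt(1 / k + 1 / (n - k))
}

#' Maximal circular t-statistic
#'
#' Scans every circular arc respecting `min_width` (both the arc and its
#' complement must have at least `min_width` bins) and returns the arc
#' maximizing `|T|`; ties are broken toward the smaller start, then smaller
#' end.
#'
#' @param x Depth vector.
#' @param min_width Minimum bins per segment.
#' @return List with `i`, `j` (1-based inclusive arc, `j < i` wraps),
#'   `t` (signed) and `t_max = |t|`; `i = j = NA` with `t_max = 0` when `x`
#'   is too short to split.
#' @export
cbs_max_t <- function(x, min_width = 2) {
  n <- length(x)
  if (n < 2 * min_width)
    return(list(i = NA_integer_, j = NA_integer_, t = 0, t_max = 0))
  r <- cbs_scan_cpp(as.numeric(x), as.integer(min_width))
  list(i = r$i + 1L, j = r$j + 1L, t = r$t, t_max = r$tmax)
}

#' Permutation threshold for the CBS split test
#'
#' Computes `T_max` for `n_perm` random permutations of `x` and returns the
#' `(1 - alpha)` empirical quantile. Uses R's RNG, so `set.seed()` makes the
#' threshold reproducible.
#'
#' @param x Depth vector.
#' @param params A [cbs_params()] object.
#' @return Critical value with attribute `perm_tmax` (the permutation
#'   distribution).
#' @export
permutation_threshold <- function(x, params = cbs_params()) {
  stopifnot(inherits(params, "cbs_params"))
  tmax <- cbs_perm_tmax_cpp(as.numeric(x), params$min_width, params$n_perm)
  structure(as.numeric(quantile(tmax, 1 - params$alpha)), perm_tmax = tmax)
}

# Sequential permutation decision: split iff (1 + exceedances)/(1 + n_perm)
# <= alpha. Early-stops as soon as the exceedance count rules the split out;
# decision-equivalent to comparing T_max against the (1-alpha) permutation
# quantile.
cbs_significant <- function(x, t_obs, params) {
  max_exceed <- floor(params$alpha * (1 + params$n_perm) - 1)
  if (max_exceed < 0) return(FALSE)
  r <- cbs_perm_count_cpp(as.numeric(x), params$min_width, params$n_perm,
                          t_obs, max_exceed)
  r[1] <= max_exceed
}

# recursive CBS on one usable stretch; returns sorted change-point cut
# positions (local, cut after bin b means boundary between b and b+1)
cbs_recurse <- function(x, lo, hi, params) {
  n <- hi - lo + 1L
  if (n < 2 * params$min_width) return(integer())
  seg <- x[lo:hi]
  mt <- cbs_max_t(seg, params$min_width)
  if (!is.finite(mt$t_max) || mt$t_max <= 0 || is.na(mt$i)) return(integer())
  if (!cbs_significant(seg, mt$t_max, params)) return(integer())
  # map arc to cut positions on [lo..hi]
  if (mt$j >= mt$i) {
    cuts <- c(if (mt$i > 1L) lo + mt$i - 2L, if (mt$j < n) lo + mt$j - 1L)
  } else {
    # wrapped arc: interior complement is [j+1 .. i-1]
    cuts <- c(lo + mt$j - 1L, lo + mt$i - 2L)
  }
  cuts <- sort(unique(cuts))
  bounds <- c(lo - 1L, cuts, hi)
  kids <- lapply(seq_len(length(bounds) - 1L), function(k)
    cbs_recurse(x, bounds[k] + 1L, bounds[k + 1L], params))
  sort(unique(c(cuts, unlist(kids))))
}

#' Circular binary segmentation of a corrected depth track
#'
#' Each contiguous stretch of usable bins is segmented independently by
#' recursive binary splitting: the arc maximizing the circular t-statistic
#' is tested against a permutation-calibrated threshold (recomputed on each
#' sub-vector); significant arcs split the stretch and the parts are
#' recursed. Segment amplitudes are per-run means of the corrected depth.
#'
#' @param track A `corrected_track`.
#' @param params A [cbs_params()] object; `params$seed` seeds the
#'   permutations.
#' @return Segment table in the same format as [segment_tvm()].
#' @export
segment_cbs <- function(track, params = cbs_params()) {
  stopifnot(inherits(track, "corrected_track"), inherits(params, "cbs_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  stretches <- usable_stretches(track$mask)
  if (nrow(stretches) == 0) return(empty_segments())
  out <- lapply(seq_len(nrow(stretches)), function(s) {
    idx <- stretches$start[s]:stretches$end[s]
    y <- track$rd[idx]
    cuts <- cbs_recurse(y, 1L, length(y), params)
    runs <- data.frame(start = c(1L, cuts + 1L), end = c(cuts, length(y)))
    runs_to_segments(runs, y, track$grid, stretches$start[s] - 1L)
  })
  do.call(rbind, out)
}
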