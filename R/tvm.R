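#' Exact 1-D total-variation denoising
#'
#' Returns the exact minimizer of
#' `0.5 * sum((y - x)^2) + lam * sum(abs(diff(x)))`,
#' a piecewise-constant signal. The objective is convex and solved by a
#' direct O(n) pass (no iteration, no tolerance).
#'
#' @param y Finite numeric signal.
#' @param lam Non-negative penalty; `lam = 0` returns `y` unchanged.
#' @return Numeric vector of fitted values, same length as `y`.
#' @export
tv_denoise <- function(y, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("lam must be a single non-negative number")
  if (!all(is.finite(y))) stop("y must be finite")
  tv_denoise_cpp(as.numeric(y), lam)
}

# maximal constant runs of a fitted signal; change-point wherever the jump
# exceeds the floating-point guard
fitted_runs <- function(x, tol = 1e-9) {
  n <- length(x)
  if (n == 0) return(data.frame(start = integer(), end = integer()))
  cp <- which(abs(diff(x)) > tol)
  start <- c(1L, cp + 1L)
  end <- c(cp, n)
  data.frame(start = start, end = end)
}

# robust noise variance from first differences (change-point tolerant)
estimate_sigma2 <- function(y) {
  if (length(y) < 3) return(max(stats::var(y), 1e-12))
  s2 <- mad(diff(y))^2 / 2
  if (!is.finite(s2) || s2 <= 0) s2 <- max(stats::var(y), 1e-12)
  s2
}

#' Schwarz information criterion of a TV fit
#'
#' `SIC = m * log(n) + RSS / sigma2`, where `m` is the number of maximal
#' constant runs of the fitted signal and the residual sum of squares is
#' computed after replacing each run's amplitude by the mean of `y` over the
#' run (re-fitting to segment means never increases the residual term).
#'
#' @param y The signal the fit was produced from.
#' @param fitted Piecewise-constant fitted values (e.g. from [tv_denoise()]).
#' @param sigma2 Noise variance; estimated robustly from `diff(y)` when
#'   omitted.
#' @param penalty_n Sample size used in the `m * log(n)` penalty; defaults
#'   to `length(y)`. When a signal is split for chunked processing, passing
#'   the full signal length keeps the penalty consistent with the unsplit
#'   problem.
#' @return SIC value with attributes `m` (segments) and `sigma2`.
#' @export
tv_sic <- function(y, fitted, sigma2 = NULL, penalty_n = NULL) {
  stopifnot(length(y) == length(fitted))
  if (is.null(sigma2)) sigma2 <- estimate_sigma2(y)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (is.null(penalty_n)) penalty_n <- length(y)
  runs <- fitted_runs(fitted)
  m <- nrow(runs)
  amps <- vapply(seq_len(m), function(k) mean(y[runs$start[k]:runs$end[k]]),
                 numeric(1))
  xt <- rep(amps, runs$end - runs$start + 1L)
  rss <- sum((y - xt)^2)
  structure(m * log(penalty_n) + rss / sigma2, m = m, sigma2 = sigma2)
}

#' Select the TV penalty by SIC minimization
#'
#' Fits [tv_denoise()] at every penalty on the grid and returns the fit with
#' minimal [tv_sic()]; ties are broken toward the larger penalty (fewer
#' segments). The default grid is 20 log-spaced values between
#' `0.1 * sigma` and `10 * sigma * sqrt(n)`.
#'
#' @param y Numeric signal.
#' @param lam_grid Non-empty vector of penalties `>= 0`, or `NULL` for the
#'   default grid.
#' @param penalty_n Sample size for the SIC penalty (see [tv_sic()]).
#' @return List with `lambda`, `fitted`, `sic`, `n_segments`, `sigma2` and
#'   the evaluated `grid`/`sic_values`.
#' @export
select_lambda <- function(y, lam_grid = NULL, penalty_n = NULL) {
  sigma2 <- estimate_sigma2(y)
  if (is.null(lam_grid)) lam_grid <- default_lambda_grid(length(y), sqrt(sigma2))
  if (length(lam_grid) == 0 || any(lam_grid < 0))
    stop("lam_grid must be a non-empty vector of non-negative penalties")
  lam_grid <- sort(lam_grid)
  sics <- numeric(length(lam_grid))
  fits <- vector("list", length(lam_grid))
  for (k in seq_along(lam_grid)) {
    fits[[k]] <- tv_denoise(y, lam_grid[k])
    sics[k] <- as.numeric(tv_sic(y, fits[[k]], sigma2, penalty_n))
  }
  best <- max(which(sics <= min(sics) + 1e-12))  # ties -> larger lambda
  fitted <- fits[[best]]
  list(lambda = lam_grid[best], fitted = fitted,
       sic = sics[best], n_segments = nrow(fitted_runs(fitted)),
       sigma2 = sigma2, grid = lam_grid, sic_values = sics)
}

default_lambda_grid <- function(n, sigma) {
  if (sigma <= 0) sigma <- 1e-6
  exp(seq(log(0.1 * sigma), log(10 * sigma * sqrt(max(n, 2))), length.out = 20))
}

# contiguous runs of TRUE in a mask: data.frame(start, end) 1-based inclusive
usable_stretches <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# build the segment table for one stretch given run boundaries on the
# stretch-local signal
runs_to_segments <- function(runs, y, grid, offset) {
  m <- nrow(runs)
  amps <- vapply(seq_len(m), function(k) mean(y[runs$start[k]:runs$end[k]]),
                 numeric(1))
  start_bin <- offset + runs$start - 1L  # 0-based global bin index
  end_bin <- offset + runs$end           # half-open
  data.frame(chrom = grid$chrom,
             start_bin = start_bin, end_bin = end_bin,
             start_bp = as.numeric(start_bin) * grid$bin_size,
             end_bp = as.numeric(end_bin) * grid$bin_size,
             amplitude = amps,
             n_bins = runs$end - runs$start + 1L,
             stringsAsFactors = FALSE)
}

empty_segments <- function() {
  data.frame(chrom = character(), start_bin = integer(), end_bin = integer(),
             start_bp = numeric(), end_bp = numeric(), amplitude = numeric(),
             n_bins = integer(), stringsAsFactors = FALSE)
}

#' Total-variation segmentation of a corrected depth track
#'
#' Each contiguous stretch of usable bins is segmented independently:
#' the penalty is chosen per stretch by [select_lambda()], change-points are
#' the jumps of the fitted signal, and each segment's amplitude is the mean
#' corrected depth over its bins.
#'
#' Because usable stretches are penalty-selected independently, the SIC
#' penalty uses the total number of usable bins on the track (not the
#' stretch length), keeping model selection consistent across stretch and
#' chunk boundaries.
#'
#' @param track A `corrected_track` (see [gc_correct_median()]).
#' @param lam_grid Optional penalty grid passed to [select_lambda()].
#' @param penalty_n SIC sample size; defaults to the number of usable bins
#'   on the track.
#' @return Segment table: `chrom`, `start_bin`/`end_bin` (0-based half-open
#'   bin indices), `start_bp`/`end_bp`, `amplitude`, `n_bins`.
#' @export
segment_tvm <- function(track, lam_grid = NULL, penalty_n = NULL) {
  stopifnot(inherits(track, "corrected_track"))
  if (is.null(penalty_n)) penalty_n <- sum(track$mask)
  stretches <- usable_stretches(track$mask)
  if (nrow(stretches) == 0) return(empty_segments())
  out <- lapply(seq_len(nrow(stretches)), function(s) {
    idx <- stretches$start[s]:stretches$end[s]
    y <- track$rd[idx]
    runs <- if (length(y) == 1) data.frame(start = 1L, end = 1L)
            else fitted_runs(select_lambda(y, lam_grid, penalty_n)$fitted)
    runs_to_segments(runs, y, track$grid, stretches$start[s] - 1L)
  })
  do.call(rbind, out)
}
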