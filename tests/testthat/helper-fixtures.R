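# shared fixtures and tiny independent oracles

# corrected track straight from a depth vector (all bins usable unless a
# mask is given)
mk_track <- function(rd, bin_size = 50, mask = NULL, chrom = "chr1") {
  grid <- compute_bins(length(rd) * bin_size, bin_size, chrom = chrom)
  mask <- if (is.null(mask)) rep(TRUE, length(rd)) else mask
  rd[!mask] <- NA_real_
  cnvdepth:::new_corrected_track(grid, rd, mask, "none",
                                 mappability = rep(1, length(rd)),
                                 gc = rep(0.45, length(rd)))
}

mk_bins <- function(raw, gc = NULL, map = NULL, bin_size = 50) {
  n <- length(raw)
  grid <- compute_bins(n * bin_size, bin_size)
  genome_bins(grid,
              raw,
              if (is.null(gc)) rep(0.45, n) else gc,
              if (is.null(map)) rep(1, n) else map)
}

tv_objective <- function(y, x, lam) 0.5 * sum((y - x)^2) + lam * sum(abs(diff(x)))

# exact TV minimum by enumerating sign patterns of adjacent differences:
# given the signs (-1, 0, +1) of x_{i+1} - x_i, each maximal equal run has
# closed-form optimal amplitude mean(y) + lam * (s_right - s_left) / len;
# the optimum over all patterns is the global TV minimum.
tv_oracle <- function(y, lam) {
  n <- length(y)
  if (n == 1) return(list(x = y, v = 0))
  pats <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), n - 1)))
  bestv <- Inf; best <- NULL
  for (r in seq_len(nrow(pats))) {
    s <- pats[r, ]
    cut <- which(s != 0)
    starts <- c(1, cut + 1); ends <- c(cut, n)
    sl <- c(0, s[cut]); sr <- c(s[cut], 0)
    x <- numeric(n)
    for (k in seq_along(starts)) {
      idx <- starts[k]:ends[k]
      x[idx] <- mean(y[idx]) + lam * (sr[k] - sl[k]) / length(idx)
    }
    v <- tv_objective(y, x, lam)
    if (v < bestv) { bestv <- v; best <- x }
  }
  list(x = best, v = bestv)
}

# exhaustive circular-arc scan in plain R
cbs_oracle_max <- function(x, min_width = 2) {
  n <- length(x)
  best <- -1
  for (i in 1:n) for (k in min_width:(n - min_width)) {
    j <- ((i - 1 + k - 1) %% n) + 1
    t <- cbs_t_statistic(x, i, j)
    if (abs(t) > best) best <- abs(t)
  }
  best
}
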