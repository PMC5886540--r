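#' Build an equal-width bin grid for one chromosome
#'
#' Bins are non-overlapping, contiguous and equal width; a trailing partial
#' bin (when the chromosome length is not a multiple of the bin size) is
#' dropped rather than truncated, so that all bins are depth-comparable.
#'
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @param chrom Chromosome name.
#' @return A `bin_grid` object with fields `chrom`, `bin_size`, `n_bins`,
#'   `chrom_length`. Bin `k` (0-based) covers `[k*bin_size, (k+1)*bin_size)`.
#' @examples
#' g <- compute_bins(1000, 100)
#' g$n_bins  # 10
#' @export
compute_bins <- function(chrom_length, bin_size, chrom = "chr1") {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1)
    stop("bin_size must be a positive integer")
  if (!is.numeric(chrom_length) || chrom_length < bin_size)
    stop("chrom_length must be >= bin_size")
  structure(
    list(chrom = as.character(chrom),
         bin_size = as.integer(bin_size),
         n_bins = as.integer(floor(chrom_length / bin_size)),
         chrom_length = as.numeric(chrom_length)),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %s, %d bins of %d bp (chrom length %.0f bp)\n",
              x$chrom, x$n_bins, x$bin_size, x$chrom_length))
  invisible(x)
}

bin_starts <- function(grid) as.numeric(seq_len(grid$n_bins) - 1L) * grid$bin_size
bin_ends <- function(grid) as.numeric(seq_len(grid$n_bins)) * grid$bin_size

#' Count reads per bin
#'
#' Each read contributes exactly one count to the bin containing its (0-based)
#' start position. Reads starting at or beyond the end of the last full bin
#' are discarded; reads on other chromosomes are skipped with a warning.
#'
#' @param reads A data frame with columns `chrom`, `start` (0-based) and
#'   `length`, e.g. from [read_reads_tsv()] or [read_reads_bam()].
#' @param grid A [compute_bins()] grid.
#' @return Integer vector of per-bin counts with attributes `n_discarded`
#'   (starts beyond the grid) and `n_unknown_chrom`.
#' @export
count_reads <- function(reads, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  stopifnot(all(c("chrom", "start") %in% names(reads)))
  on_chrom <- reads$chrom == grid$chrom
  n_unknown <- sum(!on_chrom)
  if (n_unknown > 0)
    warning(sprintf("%d reads on unknown chromosomes skipped", n_unknown))
  start <- reads$start[on_chrom]
  if (any(start < 0)) stop("negative read start positions")
  bin <- floor(start / grid$bin_size)
  keep <- bin < grid$n_bins
  counts <- tabulate(bin[keep] + 1L, nbins = grid$n_bins)
  attr(counts, "n_discarded") <- sum(!keep)
  attr(counts, "n_unknown_chrom") <- n_unknown
  counts
}

#' Configuration for the optimal-bin-size search
#'
#' @param genome_length Genome (or chromosome) length in bp.
#' @param n_reads Total number of aligned reads.
#' @param expected_gain_fraction,expected_loss_fraction Expected fraction of
#'   the genome in copy-gain / copy-loss state.
#' @param fdr Tolerated false-discovery rate for per-bin threshold calls.
#' @param dispersion Negative-binomial dispersion (variance/mean ratio) of
#'   per-bin counts; 1 means Poisson.
#' @return An `opt_bin_config` list.
#' @export
opt_bin_config <- function(genome_length, n_reads,
                           expected_gain_fraction = 0.05,
                           expected_loss_fraction = 0.05,
                           fdr = 0.01, dispersion = 3) {
  stopifnot(genome_length > 0, n_reads > 0,
            expected_gain_fraction > 0, expected_gain_fraction < 1,
            expected_loss_fraction > 0, expected_loss_fraction < 1,
            fdr > 0, fdr < 1, dispersion >= 1)
  structure(list(genome_length = genome_length, n_reads = n_reads,
                 expected_gain_fraction = expected_gain_fraction,
                 expected_loss_fraction = expected_loss_fraction,
                 fdr = fdr, dispersion = dispersion),
            class = "opt_bin_config")
}

# Central interval of a per-bin count distribution with mean lam and
# variance dispersion*lam; two-sided tail mass p_tail.
nb_central_interval <- function(lam, dispersion, p_tail) {
  if (dispersion <= 1) {
    c(qpois(p_tail / 2, lam), qpois(1 - p_tail / 2, lam))
  } else {
    size <- lam / (dispersion - 1)
    c(qnbinom(p_tail / 2, mu = lam, size = size),
      qnbinom(1 - p_tail / 2, mu = lam, size = size))
  }
}

#' Optimal bin size for a given sequencing depth
#'
#' Searches bin widths on a 50 bp grid (50-5000 bp) for the smallest width
#' whose expected per-bin read count `lambda = n_reads * w / genome_length`
#' makes copy-neutral bins separable from single-copy gain/loss at the
#' calling thresholds `0.55*lambda` and `1.45*lambda`: the central interval
#' of the negative-binomial count distribution, leaving two-sided tail mass
#' `fdr * (gain + loss fraction)` outside, must lie strictly inside the
#' thresholds. The tail budget scales the FDR by the expected variant
#' fraction so that falsely flagged copy-neutral bins stay a small fraction
#' of flagged bins.
#'
#' @param cfg An [opt_bin_config()].
#' @param grid_step,grid_min,grid_max Search grid over bin widths (bp).
#' @return Bin size in bp, with attribute `lambda` (expected reads per bin).
#' @export
optimal_bin_size <- function(cfg, grid_step = 50, grid_min = 50, grid_max = 5000) {
  stopifnot(inherits(cfg, "opt_bin_config"))
  p_tail <- cfg$fdr * (cfg$expected_gain_fraction + cfg$expected_loss_fraction)
  for (w in seq(grid_min, grid_max, by = grid_step)) {
    lam <- cfg$n_reads * w / cfg$genome_length
    ci <- nb_central_interval(lam, cfg$dispersion, p_tail)
    if (ci[1] > 0.55 * lam && ci[2] < 1.45 * lam) {
      return(structure(w, lambda = lam))
    }
  }
  stop("no bin size on the search grid separates copy states at this ",
       "coverage; higher sequencing depth is required")
}

#' Re-bin a fine score track onto a bin grid
#'
#' Per-bin score is the overlap-length-weighted mean of fine-interval scores
#' covering the bin (uncovered bases carry no weight). Bins with no coverage
#' get score 0 and are reported in the `covered` attribute so callers can
#' mask them.
#'
#' @param fine_track Data frame with columns `start`, `end` (0-based
#'   half-open) and `score` in `[0, 1]`; intervals must not overlap. A
#'   `chrom` column, if present, is filtered to the grid's chromosome.
#' @param grid A [compute_bins()] grid.
#' @return Numeric per-bin scores with logical attribute `covered`.
#' @export
rebin_scores <- function(fine_track, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  tr <- fine_track
  if ("chrom" %in% names(tr)) tr <- tr[tr$chrom == grid$chrom, , drop = FALSE]
  if (any(tr$score < 0 | tr$score > 1)) stop("scores outside [0, 1]")
  if (any(tr$end <= tr$start)) stop("malformed intervals (end <= start)")
  o <- order(tr$start)
  tr <- tr[o, , drop = FALSE]
  if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)]))
    stop("fine intervals overlap")
  w <- grid$bin_size
  glen <- as.numeric(grid$n_bins) * w
  s <- pmax(tr$start, 0); e <- pmin(tr$end, glen)
  keep <- e > s
  s <- s[keep]; e <- e[keep]; sc <- tr$score[keep]
  num <- numeric(grid$n_bins)
  den <- numeric(grid$n_bins)
  if (length(s)) {
    b1 <- floor(s / w); b2 <- floor((e - 1) / w)
    npiece <- b2 - b1 + 1
    idx <- rep.int(seq_along(s), npiece)
    bin <- unlist(lapply(seq_along(s), function(i) b1[i]:b2[i]), use.names = FALSE)
    ps <- pmax(s[idx], bin * w)
    pe <- pmin(e[idx], (bin + 1) * w)
    ov <- pe - ps
    num <- tapply_sum(ov * sc[idx], bin + 1L, grid$n_bins)
    den <- tapply_sum(ov, bin + 1L, grid$n_bins)
  }
  covered <- den > 0
  score <- ifelse(covered, num / pmax(den, 1e-300), 0)
  attr(score, "covered") <- covered
  score
}

# fast grouped sum into a fixed-length vector
tapply_sum <- function(x, group1, n) {
  out <- numeric(n)
  agg <- rowsum(x, group1)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Bundle per-bin depth and score tracks
#'
#' @param grid A [compute_bins()] grid.
#' @param raw_rd Per-bin non-negative integer read counts.
#' @param gc Per-bin GC fraction in `[0, 1]`.
#' @param mappability Per-bin mappability score in `[0, 1]`.
#' @param mask Logical usable-bin mask (default: all usable).
#' @return A `genome_bins` object.
#' @export
genome_bins <- function(grid, raw_rd, gc, mappability, mask = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  n <- grid$n_bins
  stopifnot(length(raw_rd) == n, length(gc) == n, length(mappability) == n)
  if (any(raw_rd < 0)) stop("raw_rd must be non-negative")
  if (any(gc < 0 | gc > 1)) stop("gc must be in [0, 1]")
  if (any(mappability < 0 | mappability > 1)) stop("mappability must be in [0, 1]")
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n, is.logical(mask))
  structure(list(grid = grid, raw_rd = as.numeric(raw_rd), gc = as.numeric(gc),
                 mappability = as.numeric(mappability), mask = mask),
            class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %s, %d bins x %d bp, %d usable, mean raw depth %.2f\n",
              x$grid$chrom, x$grid$n_bins, x$grid$bin_size, sum(x$mask),
              mean(x$raw_rd[x$mask])))
  invisible(x)
}
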