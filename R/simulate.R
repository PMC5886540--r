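#' Simulation configuration
#'
#' Emulates a diploid-chromosome CNV spike-in experiment at bin level:
#' a set of non-overlapping CNVs (single-copy loss, single- and two-copy
#' gain) is placed on a chromosome and per-bin read counts are drawn with a
#' GC-dependent sampling efficiency, negative-binomial noise and short
#' low-mappability stretches. The defaults are a desk-scale version of a
#' 40 Mb / 24-CNV spike-in design (4 Mb genome, same CNV number, sizes and
#' copy numbers, same 50 bp reads and bins, coverages 5-50x).
#'
#' @param genome_length Chromosome length in bp (default 4 Mb).
#' @param coverage Sequencing depth (e.g. 5, 10, 20, 30, 40, 50).
#' @param read_length Read length in bp (default 50).
#' @param bin_size Bin width in bp (default 50).
#' @param n_cnvs Number of inserted CNVs (default 24).
#' @param size_range CNV sizes are uniform on this range in bp
#'   (default 100-5000).
#' @param copy_numbers CNV copy numbers sampled uniformly from this set
#'   (default 1, 3, 4; diploid baseline is 2).
#' @param gc_bias_amplitude Depth of the GC-efficiency dip at extreme GC
#'   (0 = no bias; default 0.3).
#' @param dispersion Negative-binomial size parameter of the bin counts
#'   (`var = mu + mu^2/size`); `Inf` gives Poisson counts. The default of 30
#'   emulates read-simulator data: essentially Poisson sampling with the
#'   mild extra-Poisson variation that alignment introduces (variance/mean
#'   about 1.2 at 5x rising to about 2 at 30x).
#' @param low_map_fraction Fraction of bins placed in short low-mappability
#'   runs (default 0.02).
#' @param min_gap_bins Minimal separation between CNVs in bins (default 10).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 4e6, coverage = 30, read_length = 50,
                       bin_size = 50, n_cnvs = 24, size_range = c(100, 5000),
                       copy_numbers = c(1, 3, 4), gc_bias_amplitude = 0.3,
                       dispersion = 30, low_map_fraction = 0.02,
                       min_gap_bins = 10, seed = 1) {
  stopifnot(coverage > 0, bin_size <= min(size_range), dispersion >= 1,
            genome_length >= bin_size, size_range[1] <= size_range[2])
  structure(list(genome_length = genome_length, coverage = coverage,
                 read_length = read_length, bin_size = bin_size,
                 n_cnvs = n_cnvs, size_range = size_range,
                 copy_numbers = copy_numbers,
                 gc_bias_amplitude = gc_bias_amplitude,
                 dispersion = dispersion,
                 low_map_fraction = low_map_fraction,
                 min_gap_bins = min_gap_bins, seed = seed),
            class = "sim_config")
}

#' Simulate a ground-truth CNV set
#'
#' Places `n_cnvs` non-overlapping events with sizes uniform on
#' `size_range`, copy numbers drawn with equal weight, and at least
#' `min_gap_bins` bins of separation between events.
#'
#' @param cfg A [sim_config()].
#' @return A `truth_set`: data frame with `chrom`, `start_bp`, `end_bp`
#'   (0-based half-open), `copy_number`; attributes `genome_length`, `seed`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gap <- cfg$min_gap_bins * cfg$bin_size
  if (cfg$n_cnvs * (cfg$size_range[2] + gap) > 0.5 * cfg$genome_length)
    stop("genome too small to place the requested events")
  if (cfg$n_cnvs == 0) {
    truth <- data.frame(chrom = character(), start_bp = numeric(),
                        end_bp = numeric(), copy_number = numeric())
  } else {
    starts <- numeric(0); ends <- numeric(0)
    for (i in seq_len(cfg$n_cnvs)) {
      size <- round(runif(1, cfg$size_range[1], cfg$size_range[2]))
      repeat {
        s <- floor(runif(1, gap, cfg$genome_length - size - gap))
        if (!any(s < ends + gap & s + size + gap > starts)) break
      }
      starts <- c(starts, s); ends <- c(ends, s + size)
    }
    cn <- cfg$copy_numbers[sample.int(length(cfg$copy_numbers), cfg$n_cnvs,
                                      replace = TRUE)]
    o <- order(starts)
    truth <- data.frame(chrom = "chr1", start_bp = starts[o],
                        end_bp = ends[o], copy_number = cn[o])
  }
  structure(truth, genome_length = cfg$genome_length, seed = cfg$seed,
            class = c("truth_set", "data.frame"))
}

# GC fraction along the genome: a slowly varying isochore-like component
# (moving-average-smoothed noise, sd 0.07) plus independent bin-level
# variation (sd 0.03), matching the structure of real small-window GC
# tracks: neighbouring bins are correlated but not identical, so a GC
# equality class draws bins from across the genome.
simulate_gc_track <- function(n_bins, window = 201, jitter_sd = 0.03) {
  z <- rnorm(n_bins + window)
  sm <- as.numeric(stats::filter(z, rep(1 / window, window), sides = 2))
  sm <- sm[!is.na(sm)][seq_len(n_bins)]
  gc <- 0.45 + sm / stats::sd(sm) * 0.07 + rnorm(n_bins, 0, jitter_sd)
  pmin(pmax(gc, 0.2), 0.7)
}

# unimodal GC sampling efficiency: 1 near GC = 0.45, dipping to
# (1 - amplitude) at extreme GC
gc_efficiency <- function(gc, amplitude) {
  (1 - amplitude) + amplitude * exp(-(gc - 0.45)^2 / (2 * 0.11^2))
}

# short low-mappability runs (geometric lengths, mean run_mean bins)
simulate_mappability <- function(n_bins, low_fraction, run_mean = 10) {
  map <- rep(1, n_bins)
  n_low <- round(low_fraction * n_bins)
  placed <- 0
  while (placed < n_low) {
    len <- min(rgeom_pos(run_mean), n_low - placed)
    s <- sample.int(n_bins - len + 1L, 1L)
    map[s:(s + len - 1L)] <- runif(len, 0, 0.45)
    placed <- placed + len
  }
  map
}

rgeom_pos <- function(mean_len) {
  1L + stats::rgeom(1L, 1 / mean_len)
}

#' Simulate per-bin read counts for a truth set
#'
#' The expected count of bin `b` is
#' `coverage * bin_size / read_length * (CN_b / 2) * g(gc_b) * map_b`,
#' where `CN_b` is the overlap-weighted copy number of the bin, `g` the
#' unimodal GC-efficiency curve and `map_b` the bin's mappability score.
#' Counts are negative-binomial with the configured size parameter
#' (Poisson in the `dispersion = Inf` limit).
#'
#' @param truth A [simulate_truth()] result.
#' @param cfg The same [sim_config()].
#' @return A [genome_bins()] object (all bins unmasked; low-mappability
#'   bins carry their scores for [filter_mappability()]).
#' @export
simulate_bin_depths <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  grid <- compute_bins(cfg$genome_length, cfg$bin_size)
  n <- grid$n_bins
  gc <- simulate_gc_track(n)
  map <- simulate_mappability(n, cfg$low_map_fraction)
  cn <- rep(2, n)
  if (nrow(truth) > 0) {
    st <- bin_starts(grid); en <- bin_ends(grid)
    for (e in seq_len(nrow(truth))) {
      ov <- pmin(en, truth$end_bp[e]) - pmax(st, truth$start_bp[e])
      w <- pmax(ov, 0) / cfg$bin_size
      cn <- cn + (truth$copy_number[e] - 2) * w
    }
  }
  mu <- cfg$coverage * cfg$bin_size / cfg$read_length * (cn / 2) *
    gc_efficiency(gc, cfg$gc_bias_amplitude) * map
  counts <- draw_counts(mu, cfg$dispersion)
  genome_bins(grid, counts, gc, map)
}

draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  out <- integer(n)
  pos <- mu > 0
  if (is.infinite(dispersion)) {
    out[pos] <- rpois(sum(pos), mu[pos])
  } else {
    out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = dispersion)
  }
  out
}
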