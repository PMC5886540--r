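test_that("compute_bins builds the floor-rule grid and rejects bad input", {
  g <- compute_bins(1000, 100)
  expect_equal(g$n_bins, 10L)
  expect_equal(compute_bins(950, 100)$n_bins, 9L)  # residual 50 bp dropped
  expect_equal(compute_bins(100, 100)$n_bins, 1L)
  expect_error(compute_bins(1000, 0), "bin_size")
  expect_error(compute_bins(50, 100), "chrom_length")
})

test_that("count_reads assigns by start position and conserves reads", {
  g <- compute_bins(1000, 100)
  one <- data.frame(chrom = "chr1", start = 150, length = 50)
  counts <- count_reads(one, g)
  expect_equal(as.integer(counts), c(0L, 1L, rep(0L, 8)))

  none <- data.frame(chrom = character(), start = numeric(), length = numeric())
  expect_true(all(count_reads(none, g) == 0))

  set.seed(11)
  n <- 10000
  reads <- data.frame(chrom = "chr1", start = floor(runif(n, 0, 1000)),
                      length = 50)
  counts <- count_reads(reads, g)
  # binomial oracle: each bin ~ Bin(n, 1/10)
  sd <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(counts - n / 10) < 4 * sd))
  expect_equal(sum(counts) + attr(counts, "n_discarded") +
                 attr(counts, "n_unknown_chrom"), n)

  mixed <- data.frame(chrom = c("chr1", "chrX", "chr1"),
                      start = c(10, 10, 995), length = 50)
  expect_warning(counts <- count_reads(mixed, g), "unknown chromosome")
  expect_equal(attr(counts, "n_unknown_chrom"), 1L)
  expect_equal(sum(counts), 2L)  # 995 is inside the last bin [900,1000)
})

test_that("optimal bin size matches the lambda formula and shrinks with depth", {
  cfg <- opt_bin_config(40e6, 8e6)
  w <- optimal_bin_size(cfg)
  expect_equal(attr(w, "lambda"), 8e6 * as.numeric(w) / 40e6)
  # lambda arithmetic: 8e6 reads, 50 bp bins, 40 Mb -> 10 reads per bin
  expect_equal(8e6 * 50 / 40e6, 10)

  # Poisson-like, huge read count -> grid minimum
  tight <- opt_bin_config(40e6, 4e9, dispersion = 1)
  expect_equal(as.numeric(optimal_bin_size(tight)), 50)

  # printed-series sanity at 5x with 50 bp reads on 40 Mb (not hard-asserted)
  w5 <- as.numeric(optimal_bin_size(opt_bin_config(40e6, 40e6 * 5 / 50)))
  expect_true(w5 >= 1000 && w5 <= 2500)

  # non-increasing in coverage
  ws <- sapply(c(5, 10, 20, 30, 40, 50), function(cov)
    as.numeric(optimal_bin_size(opt_bin_config(40e6, 40e6 * cov / 50))))
  expect_true(all(diff(ws) <= 0))

  expect_error(optimal_bin_size(opt_bin_config(40e6, 100)), "coverage")
})

test_that("rebin_scores computes overlap-weighted means", {
  g <- compute_bins(1000, 100)
  uni <- data.frame(start = 0, end = 1000, score = 0.4)
  expect_equal(as.numeric(rebin_scores(uni, g)), rep(0.4, 10))

  halves <- data.frame(start = c(0, 50), end = c(50, 100),
                       score = c(0.2, 0.6))
  s <- rebin_scores(halves, g)
  expect_equal(s[1], 0.4)
  expect_false(attr(s, "covered")[2])
  expect_equal(s[2], 0)

  # random 5 bp track equals direct per-base averaging
  set.seed(3)
  fine <- data.frame(start = seq(0, 995, by = 5), end = seq(5, 1000, by = 5),
                     score = runif(200))
  s <- rebin_scores(fine, g)
  per_base <- rep(rep(fine$score, each = 5), length.out = 1000)
  oracle <- colMeans(matrix(per_base, nrow = 100))
  expect_equal(as.numeric(s), oracle, tolerance = 1e-12)

  # idempotent when fine resolution equals the grid
  coarse <- data.frame(start = seq(0, 900, 100), end = seq(100, 1000, 100),
                       score = round(runif(10), 3))
  expect_equal(as.numeric(rebin_scores(coarse, g)), coarse$score)

  expect_error(rebin_scores(data.frame(start = 0, end = 100, score = 1.2), g),
               "outside")
  expect_error(rebin_scores(data.frame(start = 100, end = 100, score = 0.5), g),
               "malformed")
})
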