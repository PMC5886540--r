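mk_segs <- function(amps, n_bins, bin_size = 50) {
  ends <- cumsum(n_bins)
  starts <- ends - n_bins
  data.frame(chrom = "chr1", start_bin = starts, end_bin = ends,
             start_bp = starts * bin_size, end_bp = ends * bin_size,
             amplitude = amps, n_bins = n_bins, stringsAsFactors = FALSE)
}

test_that("convergent_mean ignores deviant segments and falls back gracefully", {
  expect_equal(convergent_mean(mk_segs(rep(7, 5), rep(10, 5))), 7)

  # 90% of bin mass at 100, 10% at 300: converges to the 100 cluster
  segs <- mk_segs(c(100, 300), c(900, 100))
  expect_lt(abs(convergent_mean(segs) - 100) / 100, 0.01)

  # two equal halves at 100 and 300: neither survives the bounds around the
  # 200 starting mean -> weighted-median fallback with a warning
  halves <- mk_segs(c(100, 300), c(100, 100))
  expect_warning(mu <- convergent_mean(halves), "weighted median")
  expect_equal(mu, 200)  # midpoint of the even mass split
})

test_that("variant calling applies the 1.45/0.55 thresholds and the CN ratio", {
  th <- calling_thresholds(10)
  expect_equal(th$ut, 14.5)
  expect_equal(th$lt, 5.5)

  segs <- mk_segs(c(10, 20, 5, 14.4), c(50, 20, 20, 10))
  calls <- call_variants(segs, th)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$event, c(1L, 0L))
  expect_equal(calls$copy_number, c(4, 1))  # 2*amp/mean

  # amplitude equal to the mean: no call
  expect_equal(nrow(call_variants(mk_segs(10, 100), th)), 0L)
})

test_that("calling is invariant to rescaling all depths", {
  set.seed(41)
  amps <- c(30, 46, 30, 15, 30)
  segs <- mk_segs(amps, c(200, 30, 200, 25, 200))
  run <- function(s) {
    th <- calling_thresholds(convergent_mean(s))
    call_variants(s, th)
  }
  a <- run(segs)
  segs2 <- segs; segs2$amplitude <- segs$amplitude * 3.7
  b <- run(segs2)
  expect_equal(a$start_bp, b$start_bp)
  expect_equal(a$event, b$event)
  expect_equal(a$copy_number, b$copy_number)
})

test_that("gap merging follows the n/(x+y+n) rule and never mixes event types", {
  base <- data.frame(chrom = "chr1", stringsAsFactors = FALSE)
  two <- function(x, y, n, ev = c(1L, 1L), cn = c(3, 3)) {
    data.frame(chrom = "chr1",
               start_bp = c(0, x + n), end_bp = c(x, x + n + y),
               event = ev, copy_number = cn, mean_rd = cn * 5,
               stringsAsFactors = FALSE)
  }
  # 900/900 with a 200 bp gap: ratio 0.1 -> merged
  m <- merge_adjacent(two(900, 900, 200))
  expect_equal(nrow(m), 1L)
  expect_equal(m$end_bp - m$start_bp, 2000)
  # 300/300 with a 200 bp gap: ratio 0.25 -> kept apart
  expect_equal(nrow(merge_adjacent(two(300, 300, 200))), 2L)
  # duplication next to deletion is never merged
  expect_equal(nrow(merge_adjacent(two(900, 900, 0, ev = c(1L, 0L),
                                       cn = c(3, 1)))), 2L)
  # dissimilar copy numbers (rounded difference > 1) are not merged
  expect_equal(nrow(merge_adjacent(two(900, 900, 100, cn = c(3, 6)))), 2L)
  # merged copy number is the length-weighted mean
  m2 <- merge_adjacent(two(300, 900, 100, cn = c(3.0, 3.6)))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$copy_number, (300 * 3.0 + 900 * 3.6) / 1200)
  # overlapping inputs are rejected
  bad <- two(900, 900, -100)
  expect_error(merge_adjacent(bad), "overlap")
  # total called bp never decreases under merging
  set.seed(42)
  calls <- two(500, 800, 90)
  expect_gte(sum(merge_adjacent(calls)$end_bp - merge_adjacent(calls)$start_bp),
             sum(calls$end_bp - calls$start_bp))
})

test_that("call BED files round-trip byte-identically", {
  calls <- data.frame(chrom = c("chr1", "chr1"),
                      start_bp = c(100, 5000), end_bp = c(600, 9000),
                      event = c(1L, 0L), copy_number = c(3.04, 1.02),
                      mean_rd = c(30, 10), stringsAsFactors = FALSE)
  f1 <- tempfile(); f2 <- tempfile()
  write_calls_bed(calls, f1)
  expect_equal(readLines(f1)[1], "chr1\t100\t600\t1\t3.0")
  back <- read_calls_bed(f1)
  back$mean_rd <- c(30, 10)
  write_calls_bed(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # empty call set -> empty, header-less file
  f3 <- tempfile()
  write_calls_bed(calls[0, ], f3)
  expect_equal(length(readLines(f3)), 0L)
  expect_equal(nrow(read_calls_bed(f3)), 0L)
})
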