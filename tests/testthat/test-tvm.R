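test_that("tv_denoise handles degenerate penalties and simple steps", {
  y <- c(3, 1, 4, 1, 5)
  expect_equal(tv_denoise(y, 0), y)
  expect_equal(tv_denoise(rep(2.5, 8), 10), rep(2.5, 8))

  # step signal: single change-point, amplitudes shrink by lam/3 per side
  y <- c(0, 0, 0, 5, 5, 5)
  x <- tv_denoise(y, 1)
  expect_equal(x, c(rep(1 / 3, 3), rep(5 - 1 / 3, 3)))

  expect_error(tv_denoise(y, -1), "non-negative")
  expect_error(tv_denoise(c(1, NA), 1), "finite")
})

test_that("tv_denoise total variation and change-points decrease with lambda", {
  set.seed(12)
  y <- rnorm(120) + rep(c(0, 4, 0), times = c(40, 40, 40))
  lams <- c(0.1, 0.5, 1, 2, 5, 10, 40)
  tvs <- sapply(lams, function(l) sum(abs(diff(tv_denoise(y, l)))))
  cps <- sapply(lams, function(l)
    sum(abs(diff(tv_denoise(y, l))) > 1e-9))
  expect_true(all(diff(tvs) <= 1e-9))
  expect_true(all(diff(cps) <= 0))
})

test_that("tv_sic follows the penalized-residual formula", {
  # perfect fit: zero residual leaves only the segment penalty
  y <- rep(c(1, 5), each = 10)
  sic <- tv_sic(y, y, sigma2 = 1)
  expect_equal(as.numeric(sic), 2 * log(20))
  expect_equal(attr(sic, "m"), 2)

  # one segment over y = 1,2,3 with sigma2 = 1: log(3) + 2
  expect_equal(as.numeric(tv_sic(c(1, 2, 3), rep(2, 3), sigma2 = 1)),
               log(3) + 2)

  # residuals are recomputed from per-segment means of y, so a shrunk fit
  # with the same run structure scores identically
  y <- c(0, 0, 0, 5, 5, 5)
  shrunk <- tv_denoise(y, 1)
  expect_equal(as.numeric(tv_sic(y, shrunk, sigma2 = 1)),
               as.numeric(tv_sic(y, y, sigma2 = 1)))

  expect_error(tv_sic(y, y, sigma2 = 0), "positive")
})

test_that("select_lambda minimizes SIC over the grid", {
  set.seed(13)
  y <- rnorm(100, 0, 0.5) + rep(c(0, 6), each = 50)
  # brute-force oracle over the same grid
  grid <- c(0.1, 0.5, 1, 5, 20, 100)
  sics <- sapply(grid, function(l) as.numeric(tv_sic(y, tv_denoise(y, l))))
  sel <- select_lambda(y, grid)
  expect_equal(sel$sic, min(sics))

  # noiseless two-level step selects a 2-segment fit
  clean <- rep(c(1, 7), each = 20)
  expect_equal(select_lambda(clean + rnorm(40, 0, 1e-3))$n_segments, 2)

  # singleton grid is returned as-is
  expect_equal(select_lambda(y, 3.3)$lambda, 3.3)
})

test_that("select_lambda leaves pure noise unsegmented almost always", {
  # pipeline configuration: chunk-sized stretch, genome-wide SIC penalty
  set.seed(14)
  m <- replicate(200, select_lambda(rnorm(2500, 10, 2),
                                    penalty_n = 78000)$n_segments)
  expect_gte(mean(m == 1), 0.95)
})

test_that("segment_tvm tiles usable stretches with mean amplitudes", {
  tr <- mk_track(rep(10, 100))
  segs <- segment_tvm(tr)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$amplitude, 10)
  expect_equal(segs$n_bins, 100L)

  # masked gap splits the run
  mask <- rep(TRUE, 100); mask[41:50] <- FALSE
  tr2 <- mk_track(rep(10, 100), mask = mask)
  segs2 <- segment_tvm(tr2)
  expect_gte(nrow(segs2), 2L)
  expect_equal(sum(segs2$n_bins), 90L)

  # segments tile without overlap and amplitudes equal the depth means
  set.seed(15)
  y <- rnorm(400, 20, 2) + rep(c(0, 15, 0), times = c(150, 100, 150))
  tr3 <- mk_track(y)
  segs3 <- segment_tvm(tr3)
  expect_equal(segs3$start_bin[-1], segs3$end_bin[-nrow(segs3)])
  for (k in seq_len(nrow(segs3)))
    expect_equal(segs3$amplitude[k],
                 mean(y[(segs3$start_bin[k] + 1):segs3$end_bin[k]]))

  expect_equal(nrow(segment_tvm(mk_track(rep(1, 10), mask = rep(FALSE, 10)))), 0L)
})
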