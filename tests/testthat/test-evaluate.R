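mk_pred <- function(starts, ends, events) {
  data.frame(chrom = "chr1", start_bp = starts, end_bp = ends, event = events,
             copy_number = ifelse(events == 1, 3, 1), mean_rd = 1,
             stringsAsFactors = FALSE)
}
mk_truth <- function(starts, ends, cns) {
  data.frame(chrom = "chr1", start_bp = starts, end_bp = ends,
             copy_number = cns, stringsAsFactors = FALSE)
}

test_that("reciprocal-overlap matching handles boundaries and direction", {
  # 50% of each interval exactly: TP
  m <- match_events(mk_pred(100, 200, 1), mk_truth(150, 250, 3))
  expect_true(m$pred_tp)
  # 10 bp of a 300 bp truth: FP
  m2 <- match_events(mk_pred(100, 200, 1), mk_truth(190, 400, 3))
  expect_false(m2$pred_tp)
  # direction must agree
  m3 <- match_events(mk_pred(100, 200, 1), mk_truth(100, 200, 1))
  expect_false(m3$pred_tp)
  # identical sets: all TP, each truth matched once
  p <- mk_pred(c(0, 1000), c(500, 1600), c(1, 0))
  t <- mk_truth(c(0, 1000), c(500, 1600), c(4, 1))
  m4 <- match_events(p, t)
  expect_true(all(m4$pred_tp))
  expect_equal(m4$pred_truth, c(1L, 2L))
})

test_that("recall/precision/F follow their definitions", {
  # recall 0.5, precision 1 -> F = 2/3
  p <- mk_pred(0, 500, 1)
  t <- mk_truth(c(0, 5000), c(500, 5400), c(3, 3))
  s <- score_calls(p, t)
  expect_equal(s$recall, 0.5)
  expect_equal(s$precision, 1)
  expect_equal(s$f_score, 2 * 0.5 * 1 / 1.5)

  perfect <- score_calls(p, mk_truth(0, 500, 3))
  expect_equal(c(perfect$recall, perfect$precision, perfect$f_score),
               c(1, 1, 1))

  none <- score_calls(p[0, ], t)
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)

  # randomized fixture: counts match an all-pairs oracle
  set.seed(61)
  starts <- sort(sample(seq(0, 1e5, 2000), 20)) + sample(0:500, 20, TRUE)
  truth <- mk_truth(starts, starts + sample(300:1500, 20, TRUE),
                    sample(c(1, 3, 4), 20, TRUE))
  jitter <- sample(-400:400, 20, TRUE)
  pred <- mk_pred(pmax(truth$start_bp + jitter, 0),
                  truth$end_bp + sample(-200:200, 20, TRUE),
                  as.integer(truth$copy_number > 2))
  s2 <- score_calls(pred, truth)
  ok <- sapply(seq_len(nrow(pred)), function(i) {
    ov <- pmax(0, pmin(pred$end_bp[i], truth$end_bp) -
                  pmax(pred$start_bp[i], truth$start_bp))
    any(ov >= 0.5 * (pred$end_bp[i] - pred$start_bp[i]) &
          ov >= 0.5 * (truth$end_bp - truth$start_bp) &
          pred$event[i] == as.integer(truth$copy_number > 2))
  })
  expect_equal(s2$tp, sum(ok))  # one-to-one here: no double matching
})

test_that("recall and precision move monotonically with added events", {
  t <- mk_truth(c(0, 5000, 9000), c(1000, 6000, 9800), c(3, 1, 4))
  p1 <- mk_pred(0, 1000, 1)
  p2 <- rbind(p1, mk_pred(5000, 6000, 0))
  expect_gte(score_calls(p2, t)$recall, score_calls(p1, t)$recall)
  spur <- rbind(p2, mk_pred(20000, 21000, 1))
  expect_lte(score_calls(spur, t)$precision, score_calls(p2, t)$precision)
})

test_that("breakpoint error sums both boundary offsets", {
  p <- mk_pred(150, 1050, 1)
  t <- mk_truth(100, 1000, 3)
  err <- breakpoint_error(p, t)
  expect_equal(as.numeric(err), 100)
  expect_equal(attr(err, "median"), 100)
  expect_equal(as.numeric(breakpoint_error(mk_pred(100, 1000, 1), t)), 0)
  empty <- breakpoint_error(p[0, ], t)
  expect_length(empty, 0)
})

test_that("catalogue benchmarking uses l/m recall and expanded precision", {
  ann <- mk_truth(c(0, 2000, 6000), c(1000, 3000, 7000), c(3, 3, 3))
  pred <- mk_pred(c(0, 2100), c(900, 2900), c(1, 1))
  b <- benchmark_metrics(pred, ann)
  expect_equal(b$recall, 2 / 3)
  expect_equal(b$precision, 1)

  # one prediction spanning 3 annotations counts as 3 calls
  span <- mk_pred(0, 7000, 1)
  b2 <- benchmark_metrics(span, ann)
  expect_equal(b2$x, 3)
  expect_equal(b2$y, 3)
  expect_equal(b2$recall, 1)

  disjoint <- benchmark_metrics(mk_pred(50000, 51000, 1), ann)
  expect_equal(disjoint$recall, 0)
  expect_equal(disjoint$precision, 0)
})

test_that("union takes coordinate hulls; intersection takes consensus cores", {
  a <- mk_pred(c(100, 5000), c(500, 6000), c(1, 0))
  b <- mk_pred(300, 700, 1)
  u <- union_calls(a, b)
  expect_equal(nrow(u), 2L)
  expect_equal(u$start_bp[u$event == 1], 100)
  expect_equal(u$end_bp[u$event == 1], 700)   # farthest boundaries
  expect_equal(u$start_bp[u$event == 0], 5000) # A-only events retained

  same <- union_calls(a, a)
  expect_equal(same$start_bp, a$start_bp)
  expect_equal(same$end_bp, a$end_bp)

  i <- intersect_calls(a, b)
  expect_equal(nrow(i), 1L)
  expect_equal(c(i$start_bp, i$end_bp), c(300, 500))
  expect_equal(nrow(intersect_calls(a, b[0, ])), 0L)
})
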