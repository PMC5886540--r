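truth_event_type <- function(truth) as.integer(truth$copy_number > 2)

overlap_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Match predicted calls against a truth set
#'
#' A prediction is a true positive iff some truth event of the same
#' direction (gain/loss) overlaps it by at least `min_overlap` of BOTH
#' intervals (reciprocal overlap). Matching is greedy by decreasing
#' overlap; each truth event is matched at most once.
#'
#' @param pred Call table (see [call_variants()]).
#' @param truth A [simulate_truth()] result (or any data frame with
#'   `chrom`, `start_bp`, `end_bp`, `copy_number`).
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return List with `pred_tp` (logical per prediction), `pred_truth`
#'   (matched truth row index or NA), `truth_detected` (logical per truth
#'   event).
#' @export
match_events <- function(pred, truth, min_overlap = 0.5) {
  np <- nrow(pred); nt <- nrow(truth)
  pred_tp <- rep(FALSE, np)
  pred_truth <- rep(NA_integer_, np)
  truth_detected <- rep(FALSE, nt)
  if (np > 0 && nt > 0) {
    tev <- truth_event_type(truth)
    cand <- do.call(rbind, lapply(seq_len(np), function(i) {
      ov <- overlap_bp(pred$start_bp[i], pred$end_bp[i],
                       truth$start_bp, truth$end_bp)
      lp <- pred$end_bp[i] - pred$start_bp[i]
      lt <- truth$end_bp - truth$start_bp
      ok <- pred$chrom[i] == truth$chrom & pred$event[i] == tev &
        ov >= min_overlap * lp & ov >= min_overlap * lt
      if (!any(ok)) return(NULL)
      data.frame(p = i, t = which(ok), ov = ov[ok])
    }))
    if (!is.null(cand)) {
      cand <- cand[order(-cand$ov, cand$p, cand$t), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        p <- cand$p[r]; t <- cand$t[r]
        if (!pred_tp[p] && !truth_detected[t]) {
          pred_tp[p] <- TRUE
          pred_truth[p] <- t
          truth_detected[t] <- TRUE
        }
      }
    }
  }
  list(pred_tp = pred_tp, pred_truth = pred_truth,
       truth_detected = truth_detected)
}

#' Recall, precision and F-score of a prediction set
#'
#' `recall = TP / P` (P = number of truth events), `precision =
#' TP / (TP + FP)`, and the F-score is their harmonic mean. With zero
#' predictions the precision is undefined and reported as 0 with
#' `precision_defined = FALSE`; an empty truth set flags the recall the
#' same way.
#'
#' @param pred Call table.
#' @param truth Truth set.
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return A `metrics_report` list: `recall`, `precision`, `f_score`,
#'   `tp`, `fp`, `p`, `precision_defined`, `recall_defined`.
#' @export
score_calls <- function(pred, truth, min_overlap = 0.5) {
  m <- match_events(pred, truth, min_overlap)
  tp <- sum(m$pred_tp)
  fp <- nrow(pred) - tp
  p <- nrow(truth)
  precision_defined <- nrow(pred) > 0
  recall_defined <- p > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if (recall_defined) tp / p else 0
  f <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  structure(list(recall = recall, precision = precision, f_score = f,
                 tp = tp, fp = fp, p = p,
                 precision_defined = precision_defined,
                 recall_defined = recall_defined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics: recall %.3f, precision %.3f, F %.3f (TP %d, FP %d, P %d)\n",
              x$recall, x$precision, x$f_score, x$tp, x$fp, x$p))
  invisible(x)
}

#' Breakpoint error of matched calls
#'
#' For every matched prediction/truth pair, the error is
#' `|start_pred - start_truth| + |end_pred - end_truth|` in bp (summed over
#' both boundaries).
#'
#' @param pred Call table.
#' @param truth Truth set.
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return Numeric vector of per-matched-event errors (empty when nothing
#'   matches), with attributes `median` and `range`.
#' @export
breakpoint_error <- function(pred, truth, min_overlap = 0.5) {
  m <- match_events(pred, truth, min_overlap)
  sel <- which(m$pred_tp)
  if (length(sel) == 0)
    return(structure(numeric(), median = NA_real_, range = c(NA_real_, NA_real_)))
  t <- m$pred_truth[sel]
  err <- abs(pred$start_bp[sel] - truth$start_bp[t]) +
    abs(pred$end_bp[sel] - truth$end_bp[t])
  structure(err, median = median(err), range = range(err))
}

#' Recall and precision against an annotation catalogue
#'
#' Uses the either-direction overlap rule (>= 50% of the prediction or of
#' the annotation) and the asymmetric accounting for size mismatch: recall
#' is the fraction of annotations overlapped by at least one prediction
#' (adjacent predictions mapping to one annotation collapse into a single
#' call), and precision expands a prediction overlapping `m` annotations
#' into `m` true calls out of `m` counted calls (a prediction overlapping
#' nothing counts once, as false).
#'
#' @param pred Call table.
#' @param annotations Data frame with `chrom`, `start_bp`, `end_bp`.
#' @param min_overlap Overlap fraction (default 0.5).
#' @return List with `recall` (= l/m), `precision` (= x/y), and the counts
#'   `l`, `m`, `x`, `y`.
#' @export
benchmark_metrics <- function(pred, annotations, min_overlap = 0.5) {
  m_tot <- nrow(annotations)
  if (m_tot == 0 || nrow(pred) == 0) {
    return(list(recall = 0, precision = 0, l = 0, m = m_tot, x = 0,
                y = nrow(pred)))
  }
  qualifies <- function(i, j) {
    ov <- overlap_bp(pred$start_bp[i], pred$end_bp[i],
                     annotations$start_bp[j], annotations$end_bp[j])
    lp <- pred$end_bp[i] - pred$start_bp[i]
    la <- annotations$end_bp[j] - annotations$start_bp[j]
    pred$chrom[i] == annotations$chrom[j] &&
      (ov >= min_overlap * lp || ov >= min_overlap * la)
  }
  hit <- matrix(FALSE, nrow(pred), m_tot)
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(m_tot)) hit[i, j] <- qualifies(i, j)
  l <- sum(colSums(hit) > 0)
  per_pred <- rowSums(hit)
  x <- sum(per_pred)
  y <- sum(pmax(per_pred, 1))
  list(recall = l / m_tot, precision = x / y, l = l, m = m_tot, x = x, y = y)
}

#' Union of two call sets
#'
#' Keeps events detected by either workflow; overlapping events of the same
#' type are replaced by their coordinate hull (farthest start/stop
#' boundaries), with length-weighted mean copy number and depth.
#'
#' @param calls_a,calls_b Call tables.
#' @return Combined call table.
#' @export
union_calls <- function(calls_a, calls_b) {
  all <- rbind(calls_a[, c("chrom", "start_bp", "end_bp", "event",
                           "copy_number", "mean_rd")],
               calls_b[, c("chrom", "start_bp", "end_bp", "event",
                           "copy_number", "mean_rd")])
  if (nrow(all) == 0) return(empty_calls())
  out <- lapply(split(all, list(all$chrom, all$event), drop = TRUE), function(g) {
    ir <- IRanges::IRanges(start = g$start_bp + 1, end = g$end_bp)
    red <- IRanges::reduce(ir)
    grp <- S4Vectors_subjectHits(IRanges::findOverlaps(ir, red))
    lens <- g$end_bp - g$start_bp
    data.frame(chrom = g$chrom[1],
               start_bp = IRanges::start(red) - 1,
               end_bp = IRanges::end(red),
               event = g$event[1],
               copy_number = as.numeric(tapply(g$copy_number * lens, grp, sum) /
                                          tapply(lens, grp, sum)),
               mean_rd = as.numeric(tapply(g$mean_rd * lens, grp, sum) /
                                      tapply(lens, grp, sum)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersection of two call sets
#'
#' Events of the same type with at least `min_overlap` reciprocal overlap
#' across the two workflows are kept with intersected coordinates
#' (consensus); everything else is dropped.
#'
#' @param calls_a,calls_b Call tables.
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return Consensus call table.
#' @export
intersect_calls <- function(calls_a, calls_b, min_overlap = 0.5) {
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) return(empty_calls())
  rows <- list()
  for (i in seq_len(nrow(calls_a))) {
    ov <- overlap_bp(calls_a$start_bp[i], calls_a$end_bp[i],
                     calls_b$start_bp, calls_b$end_bp)
    la <- calls_a$end_bp[i] - calls_a$start_bp[i]
    lb <- calls_b$end_bp - calls_b$start_bp
    ok <- calls_b$chrom == calls_a$chrom[i] & calls_b$event == calls_a$event[i] &
      ov >= min_overlap * la & ov >= min_overlap * lb
    for (j in which(ok)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = calls_a$chrom[i],
        start_bp = max(calls_a$start_bp[i], calls_b$start_bp[j]),
        end_bp = min(calls_a$end_bp[i], calls_b$end_bp[j]),
        event = calls_a$event[i],
        copy_number = (calls_a$copy_number[i] + calls_b$copy_number[j]) / 2,
        mean_rd = (calls_a$mean_rd[i] + calls_b$mean_rd[j]) / 2,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_calls())
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}
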