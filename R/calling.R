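#' Robust chromosome mean depth by iterative convergence
#'
#' Starts from the bin-length-weighted mean amplitude over all segments and
#' iterates: recompute the weighted mean over segments whose amplitude lies
#' within `[0.55*mu, 1.45*mu]` of the previous mean, so deviant (variant)
#' segments are progressively ignored. Stops at a relative change below
#' `tol` or after `max_iter` iterations. If the exclusion empties the set,
#' falls back to the bin-length-weighted median amplitude with a warning.
#'
#' @param segments Segment table (see [segment_tvm()]).
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Converged mean depth.
#' @export
convergent_mean <- function(segments, tol = 1e-6, max_iter = 100) {
  stopifnot(nrow(segments) >= 1)
  w <- as.numeric(segments$n_bins)
  a <- segments$amplitude
  mu <- weighted.mean(a, w)
  for (it in seq_len(max_iter)) {
    keep <- a >= 0.55 * mu & a <= 1.45 * mu
    if (!any(keep)) {
      warning("iterative mean excluded every segment; ",
              "falling back to weighted median amplitude")
      return(weighted_median(a, w))
    }
    mu_new <- weighted.mean(a[keep], w[keep])
    if (abs(mu_new - mu) / max(abs(mu), 1e-12) < tol) return(mu_new)
    mu <- mu_new
  }
  mu
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  k <- which(cw >= 0.5)[1]
  if (abs(cw[k] - 0.5) < 1e-12 && k < length(x)) (x[k] + x[k + 1]) / 2
  else x[k]
}

#' Calling thresholds from a chromosome mean depth
#'
#' Upper threshold `1.45 * mean`, lower threshold `0.55 * mean`.
#'
#' @param mean_rd_chrom Converged chromosome mean depth
#'   (see [convergent_mean()]).
#' @return A `calling_thresholds` list with `mean_rd_chrom`, `ut`, `lt`.
#' @export
calling_thresholds <- function(mean_rd_chrom) {
  stopifnot(is.finite(mean_rd_chrom), mean_rd_chrom > 0)
  structure(list(mean_rd_chrom = mean_rd_chrom,
                 ut = 1.45 * mean_rd_chrom, lt = 0.55 * mean_rd_chrom),
            class = "calling_thresholds")
}

empty_calls <- function() {
  data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric(),
             event = integer(), copy_number = numeric(), mean_rd = numeric(),
             stringsAsFactors = FALSE)
}

#' Call variants from segments
#'
#' Segments with amplitude above the upper threshold become duplications
#' (`event = 1`), below the lower threshold deletions (`event = 0`); others
#' are copy-neutral and produce no call. The absolute copy number of a call
#' is `2 * amplitude / mean_rd_chrom` (real-valued).
#'
#' @param segments Segment table.
#' @param thresholds A [calling_thresholds()] object.
#' @return Call table: `chrom`, `start_bp`, `end_bp` (0-based half-open),
#'   `event` (1 duplication, 0 deletion), `copy_number`, `mean_rd`.
#' @export
call_variants <- function(segments, thresholds) {
  stopifnot(inherits(thresholds, "calling_thresholds"))
  if (nrow(segments) == 0) return(empty_calls())
  a <- segments$amplitude
  dup <- a > thresholds$ut
  del <- a < thresholds$lt
  sel <- dup | del
  if (!any(sel)) return(empty_calls())
  data.frame(chrom = segments$chrom[sel],
             start_bp = segments$start_bp[sel],
             end_bp = segments$end_bp[sel],
             event = as.integer(dup[sel]),
             copy_number = 2 * a[sel] / thresholds$mean_rd_chrom,
             mean_rd = a[sel],
             stringsAsFactors = FALSE)
}

#' Merge adjacent calls separated by small gaps
#'
#' Two consecutive calls of sizes `x` and `y` bp separated by a gap of `n`
#' bp are merged iff they are on the same chromosome, share the event type,
#' have similar copy number (rounded copy numbers differing by at most
#' `cn_diff`), and `n / (x + y + n) <= max_ratio`. Merging is applied
#' left-to-right until a fixpoint; the merged call spans both and carries
#' the length-weighted mean copy number and depth.
#'
#' @param calls Call table sorted by start within chromosome (will be
#'   sorted); overlapping calls are an error.
#' @param max_ratio Maximal gap fraction (default 0.2).
#' @param cn_diff Maximal rounded-copy-number difference (default 1).
#' @return Merged call table.
#' @export
merge_adjacent <- function(calls, max_ratio = 0.2, cn_diff = 1) {
  if (nrow(calls) < 2) return(calls)
  calls <- calls[order(calls$chrom, calls$start_bp), , drop = FALSE]
  rownames(calls) <- NULL
  same <- calls$chrom[-1] == calls$chrom[-nrow(calls)]
  if (any(same & calls$start_bp[-1] < calls$end_bp[-nrow(calls)]))
    stop("overlapping input calls")
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(calls)) {
      a <- calls[i, ]; b <- calls[i + 1L, ]
      if (a$chrom == b$chrom && a$event == b$event &&
          abs(round(a$copy_number) - round(b$copy_number)) <= cn_diff) {
        x <- a$end_bp - a$start_bp
        y <- b$end_bp - b$start_bp
        n <- b$start_bp - a$end_bp
        if (n / (x + y + n) <= max_ratio) {
          calls$end_bp[i] <- b$end_bp
          calls$copy_number[i] <- (x * a$copy_number + y * b$copy_number) / (x + y)
          calls$mean_rd[i] <- (x * a$mean_rd + y * b$mean_rd) / (x + y)
          calls <- calls[-(i + 1L), , drop = FALSE]
          rownames(calls) <- NULL
          merged <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!merged) return(calls)
  }
}

#' Write calls as 5-column BED
#'
#' Tab-separated, header-less: chromosome, start, stop, event type
#' (duplication 1, deletion 0), absolute copy number at 1 decimal.
#' Round-trips losslessly through [read_calls_bed()].
#'
#' @param calls Call table.
#' @param path Output file path.
#' @export
write_calls_bed <- function(calls, path) {
  lines <- if (nrow(calls) == 0) character() else
    sprintf("%s\t%d\t%d\t%d\t%.1f", calls$chrom,
            as.integer(calls$start_bp), as.integer(calls$end_bp),
            calls$event, calls$copy_number)
  writeLines(lines, path)
  invisible(path)
}

#' Read a 5-column BED call file written by [write_calls_bed()]
#'
#' @param path Input file path.
#' @return Call table (without `mean_rd`).
#' @export
read_calls_bed <- function(path) {
  if (file.size(path) == 0)
    return(empty_calls()[, c("chrom", "start_bp", "end_bp", "event", "copy_number")])
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start_bp", "end_bp", "event",
                                "copy_number"),
                  colClasses = c("character", "numeric", "numeric", "integer",
                                 "numeric"))
  d
}
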