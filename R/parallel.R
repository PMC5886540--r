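#' Chunked segmentation with overlap reconciliation
#'
#' Divides the bin range into `p` equal parts with `overlap` bins shared
#' between adjacent parts, segments each part independently with the chosen
#' engine, and reconciles the overlaps by keeping each change-point from the
#' chunk in whose interior (core region) it falls. Adjacent segments whose
#' amplitudes agree to a relative difference below 1e-6 are merged at the
#' seams. With `p = 1` the result is identical to serial segmentation.
#'
#' Chunk boundaries are laid out over the whole bin range; usable stretches
#' are still segmented independently, so a chunk only ever sees complete
#' pieces of the stretches it intersects.
#'
#' @param track A `corrected_track`.
#' @param engine `"tvm"` or `"cbs"`.
#' @param p Number of chunks (default 32).
#' @param overlap Bins of overlap between adjacent chunks (default 20).
#' @param ... Engine arguments: `lam_grid` for TVM, `params` for CBS.
#' @return Segment table in the format of [segment_tvm()].
#' @export
parallel_segment <- function(track, engine = c("tvm", "cbs"), p = 32,
                             overlap = 20, ...) {
  engine <- match.arg(engine)
  stopifnot(inherits(track, "corrected_track"), p >= 1)
  dots <- list(...)
  if (engine == "tvm" && is.null(dots$penalty_n))
    dots$penalty_n <- sum(track$mask)  # chunking must not weaken the SIC penalty
  seg_fun <- function(tr) {
    do.call(if (engine == "tvm") segment_tvm else segment_cbs, c(list(tr), dots))
  }
  if (p == 1) return(seg_fun(track))
  n <- track$grid$n_bins
  q <- unique(round(seq(0, n, length.out = p + 1)))  # core boundaries
  if (length(q) < 2) return(seg_fun(track))
  h <- ceiling(overlap / 2)
  chunk_len <- min(diff(q))
  if (overlap >= chunk_len)
    stop("overlap must be smaller than the chunk length")
  cuts <- integer()
  for (c in seq_len(length(q) - 1L)) {
    lo <- max(0L, q[c] - h)        # 0-based bin range [lo, hi)
    hi <- min(n, q[c + 1L] + h)
    sub <- track
    sub$mask <- track$mask & (seq_len(n) - 1L >= lo) & (seq_len(n) - 1L < hi)
    segs <- seg_fun(sub)
    if (nrow(segs) == 0) next
    # interior change-points of this chunk's segmentation (cut before
    # start_bin b means boundary b); keep those owned by the core (q[c], q[c+1]]
    b <- segs$start_bin[-1][segs$start_bin[-1] == segs$end_bin[-nrow(segs)]]
    own <- b > q[c] & b <= q[c + 1L]
    cuts <- c(cuts, b[own])
  }
  rebuild_segments(track, sort(unique(cuts)))
}

# rebuild segments of a track from a set of global cut positions (cut at bin
# b = boundary between bins b-1 and b, 0-based), per usable stretch, then
# merge seam-adjacent segments with near-identical amplitude
rebuild_segments <- function(track, cuts) {
  stretches <- usable_stretches(track$mask)
  if (nrow(stretches) == 0) return(empty_segments())
  out <- lapply(seq_len(nrow(stretches)), function(s) {
    lo <- stretches$start[s]; hi <- stretches$end[s]  # 1-based inclusive
    y <- track$rd[lo:hi]
    local_cuts <- cuts[cuts > (lo - 1L) & cuts < hi] - (lo - 1L)
    runs <- data.frame(start = c(1L, local_cuts + 1L),
                       end = c(local_cuts, length(y)))
    segs <- runs_to_segments(runs, y, track$grid, lo - 1L)
    merge_similar_segments(segs, y, lo - 1L, track$grid)
  })
  do.call(rbind, out)
}

merge_similar_segments <- function(segs, y, offset, grid, rel_tol = 1e-6) {
  repeat {
    if (nrow(segs) < 2) return(segs)
    a <- segs$amplitude[-nrow(segs)]
    b <- segs$amplitude[-1]
    rel <- abs(b - a) / pmax(abs(a), abs(b), 1e-12)
    k <- which(rel < rel_tol)
    if (length(k) == 0) return(segs)
    k <- k[1]
    segs$end_bin[k] <- segs$end_bin[k + 1]
    segs$end_bp[k] <- segs$end_bp[k + 1]
    segs$n_bins[k] <- segs$n_bins[k] + segs$n_bins[k + 1]
    segs$amplitude[k] <- mean(y[(segs$start_bin[k] - offset + 1):(segs$end_bin[k] - offset)])
    segs <- segs[-(k + 1), , drop = FALSE]
    rownames(segs) <- NULL
  }
}
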