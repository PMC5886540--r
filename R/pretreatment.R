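#' @keywords internal
new_corrected_track <- function(grid, rd, mask, method, mth = NA_real_,
                                mappability = NULL, gc = NULL,
                                flagged = NULL) {
  structure(list(grid = grid, rd = rd, mask = mask, method_tag = method,
                 mth = mth, mappability = mappability, gc = gc,
                 flagged = flagged %||% rep(FALSE, length(rd))),
            class = "corrected_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.corrected_track <- function(x, ...) {
  cat(sprintf("corrected_track: %s, %d bins, %d usable, method=%s, Mth=%s\n",
              x$grid$chrom, x$grid$n_bins, sum(x$mask), x$method_tag,
              format(x$mth)))
  invisible(x)
}

# GC equality classes at 0.001 resolution
gc_class <- function(gc) round(gc, 3)

#' Median-ratio GC-bias correction
#'
#' Corrects each bin's raw read count by the ratio of the genome-wide median
#' count to the median count of all usable bins in the same GC class
#' (GC fraction rounded to 3 decimals): `rd_i = raw_i * m / m_GC`. Classes
#' whose median is zero leave the raw value unchanged and flag the bin.
#' Masked bins carry no depth (`NA`).
#'
#' @param bins A [genome_bins()] object.
#' @return A `corrected_track` with `method_tag = "median"`.
#' @export
gc_correct_median <- function(bins) {
  stopifnot(inherits(bins, "genome_bins"))
  usable <- bins$mask
  if (!any(usable)) stop("all bins are masked")
  cls <- gc_class(bins$gc)
  m <- median(bins$raw_rd[usable])
  m_gc <- tapply(bins$raw_rd[usable], cls[usable], median)
  fac <- m / m_gc[as.character(cls)]
  flagged <- rep(FALSE, length(cls))
  bad <- usable & (!is.finite(fac) | m_gc[as.character(cls)] == 0)
  fac[bad] <- 1
  flagged[bad] <- TRUE
  rd <- bins$raw_rd * as.numeric(fac)
  rd[!usable] <- NA_real_
  new_corrected_track(bins$grid, rd, usable, "median",
                      mappability = bins$mappability, gc = bins$gc,
                      flagged = flagged)
}

#' Loess GC-bias correction
#'
#' Bins are grouped into GC classes at 0.001 resolution; a loess smoother of
#' per-class mean depth versus GC (weighted by class size) estimates the
#' GC efficiency profile. The correction is additive: the fitted class depth
#' minus the genome-wide median is subtracted from each bin, and the result
#' is re-anchored so the overall median depth is exactly preserved; negative
#' corrected values are clamped to 0. Falls back to the median method with a
#' warning when fewer than 30 distinct GC classes carry data.
#'
#' @param bins A [genome_bins()] object.
#' @param span Loess span in `(0, 1]` (degree of smoothing).
#' @return A `corrected_track` with `method_tag = "loess"`.
#' @export
gc_correct_loess <- function(bins, span = 0.75) {
  stopifnot(inherits(bins, "genome_bins"))
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("span must be in (0, 1]")
  usable <- bins$mask
  if (!any(usable)) stop("all bins are masked")
  cls <- gc_class(bins$gc)
  ucls <- sort(unique(cls[usable]))
  if (length(ucls) < 30) {
    warning("fewer than 30 GC classes with data; falling back to median method")
    return(gc_correct_median(bins))
  }
  cl_mean <- tapply(bins$raw_rd[usable], cls[usable], mean)
  cl_n <- tapply(rep(1, sum(usable)), cls[usable], sum)
  df <- data.frame(gc = as.numeric(names(cl_mean)),
                   depth = as.numeric(cl_mean), w = as.numeric(cl_n))
  fit <- loess(depth ~ gc, data = df, span = span, weights = df$w,
               degree = 2, family = "gaussian",
               control = loess.control(surface = "direct"))
  fitted_cls <- predict(fit, newdata = data.frame(gc = df$gc))
  fitted_bin <- fitted_cls[match(cls, df$gc)]
  base <- bins$raw_rd - fitted_bin
  # shift so that the overall median over usable bins is exactly preserved
  shift <- median(bins$raw_rd[usable]) - median(base[usable])
  rd <- pmax(base + shift, 0)
  rd[!usable] <- NA_real_
  new_corrected_track(bins$grid, rd, usable, "loess",
                      mappability = bins$mappability, gc = bins$gc)
}

#' @importFrom stats loess.control
NULL

#' Filter low-mappability bins
#'
#' Clears the usable mask on bins whose mappability score is `<= mth`
#' (only bins with score strictly greater than the threshold are kept).
#' `mth = 0` disables mappability filtering and keeps every bin.
#'
#' @param x A [genome_bins()] object or a `corrected_track` carrying a
#'   mappability vector.
#' @param mth Mappability cut-off in `[0, 1]` (default 0.5).
#' @return The input with its `mask` updated (and `mth` recorded on
#'   corrected tracks; masked bins of a corrected track get `NA` depth).
#' @export
filter_mappability <- function(x, mth = 0.5) {
  if (!is.numeric(mth) || length(mth) != 1L || mth < 0 || mth > 1)
    stop("mth must be in [0, 1]")
  map <- x$mappability
  if (is.null(map)) stop("no mappability scores present")
  if (mth > 0) x$mask <- x$mask & (map > mth)
  if (inherits(x, "corrected_track")) {
    x$mth <- mth
    x$rd[!x$mask] <- NA_real_
  }
  x
}
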