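#' GC profile before and after correction
#'
#' Plots mean depth per GC class (GC rounded to 2 decimals for display) for
#' the raw counts (red) and the corrected depths (blue) and writes a PNG.
#'
#' @param raw A [genome_bins()] object.
#' @param corrected A `corrected_track` on the same grid.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return The path, invisibly.
#' @export
plot_gc_profile <- function(raw, corrected, path, width = 800, height = 500) {
  stopifnot(inherits(raw, "genome_bins"), inherits(corrected, "corrected_track"))
  if (!identical(raw$grid$n_bins, corrected$grid$n_bins) ||
      !identical(raw$grid$bin_size, corrected$grid$bin_size))
    stop("mismatched bin grids")
  usable <- raw$mask & corrected$mask
  cls <- round(raw$gc[usable], 2)
  raw_prof <- tapply(raw$raw_rd[usable], cls, mean)
  cor_prof <- tapply(corrected$rd[usable], cls, mean)
  gcs <- as.numeric(names(raw_prof))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(gcs, raw_prof, type = "l", col = "red", lwd = 2,
       xlab = "GC fraction", ylab = "mean read depth",
       main = "GC profile before (red) and after (blue) correction",
       ylim = range(c(raw_prof, cor_prof), na.rm = TRUE))
  graphics::lines(gcs, cor_prof, col = "blue", lwd = 2)
  invisible(path)
}

#' Plot CNV calls along a chromosome or region
#'
#' Draws the corrected depth track with called gains shaded red and losses
#' blue, over the whole chromosome or a user-defined window, and writes a
#' PNG. A window containing no calls yields a blank depth track, not an
#' error.
#'
#' @param calls Call table.
#' @param track A `corrected_track` providing the depth signal.
#' @param chrom Chromosome to draw.
#' @param from,to Optional window in bp.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return Invisibly, the subset of calls drawn.
#' @export
plot_cnvs <- function(calls, track, chrom = track$grid$chrom, from = NULL,
                      to = NULL, path, width = 1000, height = 400) {
  stopifnot(inherits(track, "corrected_track"))
  g <- track$grid
  from <- from %||% 0
  to <- to %||% (as.numeric(g$n_bins) * g$bin_size)
  if (to <= from || from < 0) stop("invalid region")
  sub <- calls[calls$chrom == chrom & calls$start_bp < to & calls$end_bp > from,
               , drop = FALSE]
  mid <- (bin_starts(g) + bin_ends(g)) / 2
  inwin <- mid >= from & mid <= to & track$mask
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(mid[inwin], track$rd[inwin], type = "p", pch = ".", col = "grey40",
       xlab = sprintf("%s position (bp)", chrom), ylab = "corrected depth",
       xlim = c(from, to),
       main = "CNV calls (gain red, loss blue)")
  if (nrow(sub) > 0) {
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(sub))) {
      col <- if (sub$event[i] == 1) grDevices::rgb(1, 0, 0, 0.3)
             else grDevices::rgb(0, 0, 1, 0.3)
      graphics::rect(sub$start_bp[i], usr[3], sub$end_bp[i], usr[4],
                     col = col, border = NA)
    }
  }
  invisible(sub)
}
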