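#' Read a tab-separated read-placement file
#'
#' Three columns, no header: chromosome, 0-based start, read length.
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `length`.
#' @export
read_reads_tsv <- function(path) {
  read.table(path, sep = "\t", header = FALSE,
             col.names = c("chrom", "start", "length"),
             colClasses = c("character", "numeric", "numeric"))
}

#' Read aligned read placements from a BAM file
#'
#' Secondary (0x100), duplicate (0x400) and supplementary (0x800)
#' alignments are excluded; positions are converted to 0-based starts.
#' Requires the `Rsamtools` package.
#'
#' @param path Indexed BAM file.
#' @param chrom Optional chromosome to restrict to.
#' @return Data frame with columns `chrom`, `start`, `length`.
#' @export
read_reads_bam <- function(path, chrom = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM requires the Rsamtools package")
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "qwidth"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  d <- data.frame(chrom = as.character(b$rname), start = b$pos - 1,
                  length = b$qwidth, stringsAsFactors = FALSE)
  d <- d[!is.na(d$start), , drop = FALSE]
  if (!is.null(chrom)) d <- d[d$chrom == chrom, , drop = FALSE]
  d
}

#' Read a bedGraph score track
#'
#' Four columns, no header: chromosome, 0-based start, end, score. Track
#' and browser lines are skipped.
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  d <- read.table(text = lines, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "score"),
                  colClasses = c("character", "numeric", "numeric", "numeric"))
  d
}

#' Write the per-bin coordinate file
#'
#' Tab-separated with header: chrom, start, end, raw_rd, gc, mappability.
#' This is the binning stage's persisted output and the pre-treatment
#' stage's input.
#'
#' @param bins A [genome_bins()] object.
#' @param path Output path.
#' @export
write_coordinate_file <- function(bins, path) {
  stopifnot(inherits(bins, "genome_bins"))
  g <- bins$grid
  d <- data.frame(chrom = g$chrom, start = bin_starts(g), end = bin_ends(g),
                  raw_rd = bins$raw_rd, gc = bins$gc,
                  mappability = bins$mappability)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coordinate file written by [write_coordinate_file()]
#'
#' @param path Input path.
#' @return A [genome_bins()] object (mask all-usable).
#' @export
read_coordinate_file <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = c("character", rep("numeric", 5)))
  w <- d$end[1] - d$start[1]
  grid <- compute_bins(nrow(d) * w, w, chrom = d$chrom[1])
  genome_bins(grid, d$raw_rd, d$gc, d$mappability)
}

#' Write a corrected depth track
#'
#' Tab-separated with header: chrom, start, end, corrected_rd, mask.
#'
#' @param track A `corrected_track`.
#' @param path Output path.
#' @export
write_corrected <- function(track, path) {
  stopifnot(inherits(track, "corrected_track"))
  g <- track$grid
  d <- data.frame(chrom = g$chrom, start = bin_starts(g), end = bin_ends(g),
                  corrected_rd = track$rd, mask = as.integer(track$mask))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a corrected depth track written by [write_corrected()]
#'
#' @param path Input path.
#' @return A `corrected_track` (method tag `"file"`).
#' @export
read_corrected <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = c("character", rep("numeric", 4)))
  w <- d$end[1] - d$start[1]
  grid <- compute_bins(nrow(d) * w, w, chrom = d$chrom[1])
  new_corrected_track(grid, d$corrected_rd, d$mask > 0, "file")
}

#' Write a segment table
#'
#' Tab-separated with header: chrom, start_bp, end_bp, amplitude, n_bins.
#'
#' @param segments Segment table (see [segment_tvm()]).
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  d <- segments[, c("chrom", "start_bp", "end_bp", "amplitude", "n_bins")]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#'
#' @param path Input path.
#' @param bin_size Bin width used to reconstruct bin indices.
#' @return Segment table.
#' @export
read_segments <- function(path, bin_size) {
  d <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = c("character", rep("numeric", 4)))
  d$start_bin <- as.integer(d$start_bp / bin_size)
  d$end_bin <- as.integer(d$end_bp / bin_size)
  d$n_bins <- as.integer(d$n_bins)
  d[, c("chrom", "start_bin", "end_bin", "start_bp", "end_bp", "amplitude",
        "n_bins")]
}
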