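#' Assemble a pipeline configuration
#'
#' @param reads Path to a read-placement TSV (chrom, 0-based start, length)
#'   or an indexed BAM file.
#' @param gc,map Paths to bedGraph score tracks (GC fraction, mappability).
#' @param out_dir Output directory (created if missing).
#' @param chrom Chromosome to analyse.
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp (default 100).
#' @param gc_method `"none"`, `"median"` or `"loess"`.
#' @param mth Mappability cut-off (default 0.5; 0 disables filtering).
#' @param engines Segmentation engines to run (`"tvm"`, `"cbs"`, or both).
#' @param combine_mode `"single"`, `"union"` or `"intersection"` for
#'   combining two engines' calls.
#' @param p,overlap Chunking parameters for [parallel_segment()].
#' @param cbs_alpha,cbs_n_perm,min_width CBS parameters.
#' @param merge_ratio Gap-merge ratio (default 0.2).
#' @param tracks Optional annotation-manifest path (see
#'   [read_track_manifest()]).
#' @param make_plots Write GC-profile and CNV plots (default TRUE).
#' @param seed RNG seed (default 42).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reads, gc, map, out_dir, chrom, chrom_length,
                            bin_size = 100, gc_method = c("median", "loess", "none"),
                            mth = 0.5, engines = c("tvm", "cbs"),
                            combine_mode = c("union", "intersection", "single"),
                            p = 32, overlap = 20, cbs_alpha = 0.01,
                            cbs_n_perm = 10000, min_width = 2,
                            merge_ratio = 0.2, tracks = NULL,
                            make_plots = TRUE, seed = 42) {
  gc_method <- match.arg(gc_method)
  combine_mode <- match.arg(combine_mode)
  engines <- match.arg(engines, c("tvm", "cbs"), several.ok = TRUE)
  if (length(engines) == 1) combine_mode <- "single"
  stopifnot(bin_size >= 1, mth >= 0, mth <= 1, merge_ratio >= 0,
            chrom_length >= bin_size)
  structure(list(reads = reads, gc = gc, map = map, out_dir = out_dir,
                 chrom = chrom, chrom_length = chrom_length,
                 bin_size = bin_size, gc_method = gc_method, mth = mth,
                 engines = engines, combine_mode = combine_mode, p = p,
                 overlap = overlap, cbs_alpha = cbs_alpha,
                 cbs_n_perm = cbs_n_perm, min_width = min_width,
                 merge_ratio = merge_ratio, tracks = tracks,
                 make_plots = make_plots, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full CNV-calling pipeline
#'
#' Executes prepare (binning + score re-binning), pre-treatment (GC
#' correction + mappability filtering), segmentation with one or both
#' engines, variant calling with gap merging, optional union/intersection
#' combination, optional annotation and plots. Every stage's output is
#' persisted under `cfg$out_dir`; a run log records the configuration and
#' seed. Reruns with the same configuration and seed are byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `calls`, per-engine calls and segments,
#'   the corrected track and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  # prepare
  reads <- if (grepl("\\.bam$", cfg$reads, ignore.case = TRUE))
    read_reads_bam(cfg$reads, cfg$chrom) else read_reads_tsv(cfg$reads)
  grid <- compute_bins(cfg$chrom_length, cfg$bin_size, chrom = cfg$chrom)
  counts <- count_reads(reads, grid)
  gc <- rebin_scores(read_bedgraph(cfg$gc), grid)
  map <- rebin_scores(read_bedgraph(cfg$map), grid)
  mask <- attr(gc, "covered") & attr(map, "covered")
  bins <- genome_bins(grid, counts, gc, map, mask = mask)
  write_coordinate_file(bins, file.path(cfg$out_dir, "coordinates.tsv"))

  # pretreat
  bins <- filter_mappability(bins, cfg$mth)
  track <- switch(cfg$gc_method,
                  median = gc_correct_median(bins),
                  loess = gc_correct_loess(bins),
                  none = new_corrected_track(bins$grid, {
                    rd <- bins$raw_rd; rd[!bins$mask] <- NA_real_; rd
                  }, bins$mask, "none", mth = cfg$mth,
                  mappability = bins$mappability, gc = bins$gc))
  track$mth <- cfg$mth
  write_corrected(track, file.path(cfg$out_dir, "corrected.tsv"))

  # segment + call per engine
  per_engine <- list()
  for (eng in cfg$engines) {
    segs <- if (eng == "tvm") {
      parallel_segment(track, "tvm", p = cfg$p, overlap = cfg$overlap)
    } else {
      parallel_segment(track, "cbs", p = cfg$p, overlap = cfg$overlap,
                       params = cbs_params(alpha = cfg$cbs_alpha,
                                           n_perm = cfg$cbs_n_perm,
                                           min_width = cfg$min_width,
                                           seed = cfg$seed))
    }
    write_segments(segs, file.path(cfg$out_dir, sprintf("segments_%s.tsv", eng)))
    th <- calling_thresholds(convergent_mean(segs))
    calls <- merge_adjacent(call_variants(segs, th), max_ratio = cfg$merge_ratio)
    write_calls_bed(calls, file.path(cfg$out_dir, sprintf("calls_%s.bed", eng)))
    per_engine[[eng]] <- list(segments = segs, thresholds = th, calls = calls)
  }

  calls <- if (length(cfg$engines) == 1) {
    per_engine[[1]]$calls
  } else if (cfg$combine_mode == "union") {
    union_calls(per_engine[[1]]$calls, per_engine[[2]]$calls)
  } else if (cfg$combine_mode == "intersection") {
    intersect_calls(per_engine[[1]]$calls, per_engine[[2]]$calls)
  } else {
    per_engine[[1]]$calls
  }
  write_calls_bed(calls, file.path(cfg$out_dir, "calls.bed"))

  annotated <- NULL
  if (!is.null(cfg$tracks)) {
    annotated <- annotate_calls(calls, read_track_manifest(cfg$tracks))
    write_annotated(annotated, file.path(cfg$out_dir, "annotated.tsv"))
  }
  if (isTRUE(cfg$make_plots)) {
    if (cfg$gc_method != "none")
      plot_gc_profile(bins, track, file.path(cfg$out_dir, "gc_profile.png"))
    plot_cnvs(calls, track, path = file.path(cfg$out_dir, "cnv_calls.png"))
  }

  log <- c(sprintf("cnvdepth %s", as.character(utils::packageVersion("cnvdepth"))),
           sprintf("seed: %d", cfg$seed),
           sprintf("config: %s", paste(deparse(cfg[setdiff(names(cfg), "tracks")]),
                                       collapse = " ")))
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(calls = calls, per_engine = per_engine, track = track,
                 annotated = annotated, out_dir = cfg$out_dir))
}
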