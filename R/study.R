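#' Run one simulated CNV-detection replicate
#'
#' Simulates truth and bin depths under `cfg`, applies median GC correction
#' and mappability filtering at `mth`, segments with the requested engine
#' (chunked via [parallel_segment()]), and calls variants with ratio-threshold
#' thresholding and gap merging.
#'
#' @param cfg A [sim_config()].
#' @param engine `"tvm"` or `"cbs"`.
#' @param mth Mappability cut-off (default 0.5).
#' @param p,overlap Chunking parameters (defaults 32 and 20 bins).
#' @param cbs A [cbs_params()] for the CBS engine.
#' @param merge_ratio Gap-merge ratio (default 0.2).
#' @return List with `truth`, `calls`, `segments`, `track`, `thresholds`.
#' @export
run_replicate <- function(cfg, engine = c("tvm", "cbs"), mth = 0.5, p = 32,
                          overlap = 20, cbs = cbs_params(), merge_ratio = 0.2) {
  engine <- match.arg(engine)
  truth <- simulate_truth(cfg)
  bins <- simulate_bin_depths(truth, cfg)
  bins <- filter_mappability(bins, mth)
  track <- gc_correct_median(bins)
  segs <- if (engine == "tvm") {
    parallel_segment(track, "tvm", p = p, overlap = overlap)
  } else {
    set.seed(cbs$seed)
    parallel_segment(track, "cbs", p = p, overlap = overlap, params = cbs)
  }
  mu <- convergent_mean(segs)
  th <- calling_thresholds(mu)
  calls <- merge_adjacent(call_variants(segs, th), max_ratio = merge_ratio)
  list(truth = truth, calls = calls, segments = segs, track = track,
       thresholds = th)
}

subset_by_size <- function(d, min_bp = NULL, max_bp = NULL) {
  len <- d$end_bp - d$start_bp
  keep <- rep(TRUE, nrow(d))
  if (!is.null(min_bp)) keep <- keep & len > min_bp
  if (!is.null(max_bp)) keep <- keep & len <= max_bp
  d[keep, , drop = FALSE]
}

score_size_class <- function(calls, truth, min_bp = NULL, max_bp = NULL) {
  score_calls(subset_by_size(calls, min_bp, max_bp),
              subset_by_size(truth, min_bp, max_bp))
}

#' Run the simulated benchmark study
#'
#' For each coverage and seed, simulates a replicate genome and evaluates
#' both (or one) segmentation engine: F/recall/precision for the small
#' (<= 1 Kb) and large (> 1 Kb) truth subsets, per-event-type F for large
#' events, and breakpoint errors of all matched calls. Within a size class,
#' predictions are restricted to the same class before matching.
#'
#' @param coverages Coverages to simulate.
#' @param n_seeds Replicates per coverage.
#' @param base_seed Replicate `r` at any coverage uses seed
#'   `base_seed + 1000 * r`.
#' @param engines Engines to run.
#' @param cfg_args Extra arguments passed to [sim_config()].
#' @param cbs_n_perm,cbs_alpha Permutation-test size for the CBS engine
#'   (desk-scale default 200 permutations at alpha 0.01).
#' @return Data frame with one row per coverage x seed x engine and columns
#'   for the metrics; breakpoint errors are in the `bp_errors` list column.
#' @export
run_simulation_study <- function(coverages = c(5, 10, 20, 30), n_seeds = 10,
                                 base_seed = 1, engines = c("tvm", "cbs"),
                                 cfg_args = list(), cbs_n_perm = 200,
                                 cbs_alpha = 0.01) {
  rows <- list()
  for (cov in coverages) {
    for (r in seq_len(n_seeds)) {
      seed <- base_seed + 1000L * r
      cfg <- do.call(sim_config, c(list(coverage = cov, seed = seed), cfg_args))
      for (eng in engines) {
        res <- run_replicate(cfg, engine = eng,
                             cbs = cbs_params(alpha = cbs_alpha,
                                              n_perm = max(cbs_n_perm, 100),
                                              seed = seed))
        small <- score_size_class(res$calls, res$truth, max_bp = 1000)
        large <- score_size_class(res$calls, res$truth, min_bp = 1000)
        truth_l <- subset_by_size(res$truth, min_bp = 1000)
        calls_l <- subset_by_size(res$calls, min_bp = 1000)
        gain <- score_calls(calls_l[calls_l$event == 1, , drop = FALSE],
                            truth_l[truth_l$copy_number > 2, , drop = FALSE])
        loss <- score_calls(calls_l[calls_l$event == 0, , drop = FALSE],
                            truth_l[truth_l$copy_number < 2, , drop = FALSE])
        m <- match_events(res$calls, res$truth)
        cn_pred <- res$calls$copy_number[m$pred_tp]
        cn_true <- res$truth$copy_number[m$pred_truth[m$pred_tp]]
        err <- breakpoint_error(res$calls, res$truth)
        rows[[length(rows) + 1L]] <- data.frame(
          coverage = cov, seed = seed, engine = eng,
          f_small = small$f_score, recall_small = small$recall,
          precision_small = small$precision,
          precision_small_defined = small$precision_defined,
          f_large = large$f_score, recall_large = large$recall,
          precision_large = large$precision,
          f_gain_large = gain$f_score, f_loss_large = loss$f_score,
          n_calls = nrow(res$calls),
          cn_within_half = sum(abs(cn_pred - cn_true) <= 0.5),
          cn_matched = length(cn_pred),
          bp_errors = I(list(as.numeric(err))),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
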