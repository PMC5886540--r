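#' Build an annotation track
#'
#' Categories follow the annotation scheme of the pipeline: `functional`
#' elements (genes, enhancers, lincRNA, miRNA target sites) match on any
#' base-pair of overlap and confer medium priority; `clinical` associations
#' (pathogenic variants, disease genes, haploinsufficiency, intolerance)
#' confer high priority; `known` population CNVs (DGV) require half-of-CNV
#' overlap and confer low priority; `structural` features (repeats,
#' segmental duplications, heterochromatin) are reported but never set
#' priority. The overlap rule defaults per category (`clinical` defaults to
#' `half_of_cnv`; haploinsufficiency/intolerance tracks should pass
#' `overlap_rule = "any_bp"`).
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `label`.
#' @param category One of `"functional"`, `"clinical"`, `"known"`,
#'   `"structural"`.
#' @param name Track name.
#' @param overlap_rule `"any_bp"` (>= 1 bp of overlap) or `"half_of_cnv"`
#'   (overlap >= 50% of the CNV's length); default per category.
#' @param priority_class Override of the category's priority class.
#' @return An `annotation_track` object.
#' @export
annotation_track <- function(intervals, category = c("functional", "clinical",
                                                     "known", "structural"),
                             name = category,
                             overlap_rule = NULL, priority_class = NULL) {
  category <- match.arg(category)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end <= intervals$start))
    stop("malformed track interval (end <= start)")
  if (is.null(intervals$label))
    intervals$label <- paste0(name, "_", seq_len(nrow(intervals)))
  defaults <- list(functional = list(rule = "any_bp", prio = "medium"),
                   clinical = list(rule = "half_of_cnv", prio = "high"),
                   known = list(rule = "half_of_cnv", prio = "low"),
                   structural = list(rule = "half_of_cnv", prio = "none"))
  rule <- overlap_rule %||% defaults[[category]]$rule
  prio <- priority_class %||% defaults[[category]]$prio
  rule <- match.arg(rule, c("any_bp", "half_of_cnv"))
  prio <- match.arg(prio, c("high", "medium", "low", "none"))
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name, category = category, overlap_rule = rule,
                 priority_class = prio, intervals = intervals),
            class = "annotation_track")
}

# overlap widths between one call and all track intervals on its chromosome
call_overlaps <- function(call, intervals) {
  iv <- intervals[intervals$chrom == call$chrom, , drop = FALSE]
  if (nrow(iv) == 0) return(iv[, c("start", "end", "label")][0, ])
  q <- IRanges::IRanges(start = call$start_bp + 1, end = call$end_bp)
  s <- IRanges::IRanges(start = iv$start + 1, end = iv$end)
  hits <- IRanges::findOverlaps(q, s)
  idx <- S4Vectors_subjectHits(hits)
  if (length(idx) == 0) return(iv[0, c("start", "end", "label")])
  ov <- IRanges::width(IRanges::pintersect(rep(q, length(idx)), s[idx]))
  out <- iv[idx, c("start", "end", "label"), drop = FALSE]
  out$overlap_bp <- ov
  out
}

# avoid importing S4Vectors just for accessors
S4Vectors_subjectHits <- function(hits) {
  as.data.frame(hits)$subjectHits
}

#' Features of one annotation track hit by a call
#'
#' Applies the track's overlap rule: `any_bp` matches on >= 1 bp of
#' overlap, `half_of_cnv` requires the overlap to cover at least 50% of the
#' call's length.
#'
#' @param call One-row call table (see [call_variants()]).
#' @param track An [annotation_track()].
#' @return Data frame of matched features with `label` and `overlap_bp`.
#' @export
overlap_hits <- function(call, track) {
  stopifnot(inherits(track, "annotation_track"))
  ov <- call_overlaps(call, track$intervals)
  if (nrow(ov) == 0) return(data.frame(label = character(), overlap_bp = numeric()))
  len <- call$end_bp - call$start_bp
  keep <- if (track$overlap_rule == "any_bp") ov$overlap_bp >= 1
          else ov$overlap_bp >= 0.5 * len
  data.frame(label = ov$label[keep], overlap_bp = ov$overlap_bp[keep],
             stringsAsFactors = FALSE)
}

#' Annotate calls against a set of tracks
#'
#' @param calls Call table.
#' @param tracks List of [annotation_track()] objects.
#' @return List of `annotated_call` objects, each with the call row, its
#'   hits (per track: category, track name, feature label, overlap bp) and
#'   the assigned priority.
#' @export
annotate_calls <- function(calls, tracks) {
  stopifnot(is.list(tracks))
  lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, , drop = FALSE]
    hits <- do.call(rbind, lapply(tracks, function(tr) {
      h <- overlap_hits(call, tr)
      if (nrow(h) == 0) return(NULL)
      data.frame(track = tr$name, category = tr$category,
                 priority_class = tr$priority_class,
                 label = h$label, overlap_bp = h$overlap_bp,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(hits))
      hits <- data.frame(track = character(), category = character(),
                         priority_class = character(), label = character(),
                         overlap_bp = numeric(), stringsAsFactors = FALSE)
    ann <- structure(list(call = call, hits = hits, priority = NA_character_),
                     class = "annotated_call")
    ann$priority <- assign_priority(ann)
    ann
  })
}

#' Priority of an annotated call
#'
#' Clinical hits dominate: any clinical hit gives high priority. A novel
#' call (no known-CNV hit) spanning a functional element gets medium
#' priority; a call overlapping a known population CNV gets low priority.
#' Structural hits never set priority; a call with no qualifying hits is
#' unprioritized.
#'
#' @param annotated An `annotated_call` (see [annotate_calls()]).
#' @return One of `"high"`, `"medium"`, `"low"`, `"unprioritized"`.
#' @export
assign_priority <- function(annotated) {
  cats <- annotated$hits$category
  if ("clinical" %in% cats) return("high")
  if ("functional" %in% cats && !("known" %in% cats)) return("medium")
  if ("known" %in% cats) return("low")
  "unprioritized"
}

#' Write annotated calls as TSV
#'
#' Call columns plus semicolon-joined `hits` (`track:label:overlap_bp`) and
#' `priority`.
#'
#' @param annotated List from [annotate_calls()].
#' @param path Output path.
#' @export
write_annotated <- function(annotated, path) {
  rows <- lapply(annotated, function(a) {
    hits <- if (nrow(a$hits) == 0) "" else
      paste(sprintf("%s:%s:%d", a$hits$track, a$hits$label,
                    as.integer(a$hits$overlap_bp)), collapse = ";")
    cbind(a$call[, c("chrom", "start_bp", "end_bp", "event", "copy_number")],
          hits = hits, priority = a$priority)
  })
  d <- do.call(rbind, rows)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation-track manifest
#'
#' YAML list of entries with fields `path` (BED-like TSV: chrom, start,
#' end, optional label), `category`, `name`, and optional `overlap_rule`
#' and `priority_class`.
#'
#' @param path Manifest path; relative track paths are resolved against the
#'   manifest's directory.
#' @return List of [annotation_track()] objects.
#' @export
read_track_manifest <- function(path) {
  entries <- yaml::read_yaml(path)
  base <- dirname(path)
  lapply(entries, function(e) {
    p <- e$path
    if (!file.exists(p)) p <- file.path(base, e$path)
    iv <- read.table(p, sep = "\t", header = FALSE, fill = TRUE,
                     stringsAsFactors = FALSE)
    names(iv)[1:3] <- c("chrom", "start", "end")
    if (ncol(iv) >= 4) names(iv)[4] <- "label"
    annotation_track(iv, category = e$category,
                     name = e$name %||% e$category,
                     overlap_rule = e$overlap_rule,
                     priority_class = e$priority_class)
  })
}
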