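call_row <- function(start, end, event = 1L) {
  data.frame(chrom = "chr1", start_bp = start, end_bp = end, event = event,
             copy_number = if (event == 1) 3 else 1, mean_rd = 20,
             stringsAsFactors = FALSE)
}

test_that("overlap rules honour the any-bp and half-of-CNV criteria", {
  feat <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  any_tr <- annotation_track(feat(199, 300), "functional", name = "genes")
  # 1 bp of overlap is enough under any_bp
  expect_equal(nrow(overlap_hits(call_row(100, 200), any_tr)), 1L)
  expect_equal(nrow(overlap_hits(call_row(100, 199), any_tr)), 0L)

  half_tr <- annotation_track(feat(150, 400), "known", name = "dgv")
  # overlap of exactly 50% of the call qualifies
  expect_equal(nrow(overlap_hits(call_row(100, 200), half_tr)), 1L)
  expect_equal(nrow(overlap_hits(call_row(100, 201), half_tr)), 1L)
  expect_equal(nrow(overlap_hits(call_row(98, 200), half_tr)), 0L)

  expect_error(annotation_track(feat(100, 100), "known"), "malformed")
})

test_that("hit sets match a quadratic all-pairs scan", {
  set.seed(51)
  n <- 100
  calls <- data.frame(chrom = "chr1",
                      start_bp = sort(sample(0:100000, n)) * 1,
                      stringsAsFactors = FALSE)
  calls$end_bp <- calls$start_bp + sample(100:2000, n, replace = TRUE)
  calls$event <- 1L; calls$copy_number <- 3; calls$mean_rd <- 1
  iv <- data.frame(chrom = "chr1", start = sample(0:100000, n))
  iv$end <- iv$start + sample(100:3000, n, replace = TRUE)
  tr <- annotation_track(iv, "clinical", name = "clinvar")
  for (i in sample(n, 12)) {
    got <- overlap_hits(calls[i, ], tr)
    ov <- pmax(0, pmin(calls$end_bp[i], sort(iv$end)) -
                  pmax(calls$start_bp[i], sort(iv$start)))
    # oracle: brute force over unsorted track rows
    ivs <- tr$intervals
    ovb <- pmax(0, pmin(calls$end_bp[i], ivs$end) -
                   pmax(calls$start_bp[i], ivs$start))
    want <- sum(ovb >= 0.5 * (calls$end_bp[i] - calls$start_bp[i]))
    expect_equal(nrow(got), want)
  }
})

test_that("priorities follow clinical > functional(novel) > known precedence", {
  feat <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  clin <- annotation_track(feat(0, 1000), "clinical", name = "clinvar")
  fun <- annotation_track(feat(0, 1000), "functional", name = "genes")
  known <- annotation_track(feat(0, 1000), "known", name = "dgv")
  struct <- annotation_track(feat(0, 1000), "structural", name = "repeats")
  call <- call_row(200, 800)

  pr <- function(tracks) annotate_calls(call, tracks)[[1]]$priority
  expect_equal(pr(list(clin, known)), "high")     # clinical dominates
  expect_equal(pr(list(fun)), "medium")
  expect_equal(pr(list(known)), "low")
  expect_equal(pr(list(fun, known)), "low")       # not novel -> not medium
  expect_equal(pr(list(struct)), "unprioritized") # structural never sets it
  expect_equal(pr(list()), "unprioritized")

  # monotone: adding a clinical hit never lowers priority
  expect_equal(pr(list(fun, known, clin)), "high")
})

test_that("annotation is invariant under a genome-wide shift", {
  feat <- data.frame(chrom = "chr1", start = c(100, 900), end = c(400, 1400))
  tr0 <- annotation_track(feat, "functional")
  tr1 <- annotation_track(transform(feat, start = start + 5000,
                                    end = end + 5000), "functional")
  c0 <- overlap_hits(call_row(200, 1000), tr0)
  c1 <- overlap_hits(call_row(5200, 6000), tr1)
  expect_equal(c0$overlap_bp, c1$overlap_bp)
})

test_that("track manifests round through YAML and BED", {
  d <- tempfile(); dir.create(d)
  bed <- file.path(d, "genes.bed")
  writeLines("chr1\t100\t500\tGENE1\nchr1\t900\t1200\tGENE2", bed)
  manifest <- file.path(d, "tracks.yaml")
  yaml::write_yaml(list(list(path = "genes.bed", category = "functional",
                             name = "genes")), manifest)
  tracks <- read_track_manifest(manifest)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$overlap_rule, "any_bp")
  expect_equal(tracks[[1]]$priority_class, "medium")
  ann <- annotate_calls(call_row(450, 950), tracks)
  expect_equal(ann[[1]]$hits$label, c("GENE1", "GENE2"))
  expect_equal(ann[[1]]$priority, "medium")
})
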