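# cnvdepth

Copy number variant (CNV) detection from the depth-of-coverage signal of
whole-genome sequencing data, for analysts who have coordinate-sorted
alignments (or plain read placements) and want called duplications and
deletions with absolute copy numbers, annotations and benchmark metrics.

Read depth is proportional to local copy number. `cnvdepth` bins the
genome into equal-width windows, counts reads per bin, corrects GC bias
(median-ratio `r̃ᵢ = rᵢ·m/m_GC`, or an additive median-preserving loess)
and masks low-mappability bins (score ≤ M<sub>th</sub>, default 0.5). The
corrected signal is segmented by either of two change-point engines:

* **TVM** — the exact minimizer of the total-variation penalized least
  squares `½Σ(yᵢ−xᵢ)² + λΣ|xᵢ₊₁−xᵢ|`, with the penalty chosen by the
  Schwarz information criterion `SIC(λ) = m·ln(n) + Σ(yᵢ−x̃ᵢ)²/σ²`
  (amplitudes re-fit to segment means);
* **CBS** — circular binary segmentation: recursive splitting at the arc
  maximizing `T = (μ_arc − μ_rest)/√(1/n_arc + 1/(n−n_arc))`, calibrated
  by a permutation test.

Segments with mean depth above `1.45×μ` (below `0.55×μ`) of a robust,
iteratively converged chromosome mean μ are reported as duplications
(deletions) with absolute copy number `2·depth/μ`; nearby same-type calls
merge when the gap fraction `n/(x+y+n) ≤ 0.2`. Calls can be combined
across engines (union with farthest boundaries, or consensus
intersection), annotated against functional/clinical/known/structural
tracks with high/medium/low priorities, and plotted. A bin-level
simulation module spikes 24 CNVs (100–5000 bp, copy numbers 1/3/4) into a
diploid chromosome with GC-dependent sampling efficiency and
negative-binomial noise, and the evaluation module scores calls by 50%
reciprocal overlap (recall, precision, F-score, breakpoint error).

## Worked example

Simulate a 4 Mb diploid chromosome at 30× with 24 spiked CNVs, run the
CBS workflow (median GC correction, M<sub>th</sub> = 0.5, chunked
segmentation, threshold calling with gap merging), and score the calls:

```r
library(cnvdepth)
cfg <- sim_config(coverage = 30, seed = 1001)
res <- run_replicate(cfg, engine = "cbs",
                     cbs = cbs_params(n_perm = 200, seed = 1001))
score_calls(res$calls, res$truth)
#> metrics: recall 0.917, precision 0.957, F 0.936 (TP 22, FP 1, P 24)
head(res$calls, 3)
#>   chrom start_bp end_bp event copy_number  mean_rd
#> 1  chr1     7600  11500     1   3.9952438 56.81973
#> 2  chr1   352100 355700     0   1.0108887 14.37670
#> 3  chr1   495800 496650     0   1.0233131 14.55340
```

22 of the 24 spiked events are recovered at 50% reciprocal overlap with
one false call; the first call is a two-copy gain (copy number ≈ 4.0
against the diploid baseline of 2) and the next two are single-copy
deletions. `write_calls_bed()` emits these as 5-column BED
(chrom, start, stop, event 1 = duplication / 0 = deletion, copy number at
one decimal).

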