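---
title: "Methods: hit calling in ORF-overexpression transcriptomic screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hit calling in ORF-overexpression transcriptomic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfscreen)
```

## The screening problem

An ORF-overexpression screen stably transduces a panel of candidate
protein-coding sequences (ORFs) into a cell-line model — one lentiviral
construct per condition, several independent infections (replicates) per ORF,
the panel organised in experimental batches, each batch carrying its own
empty-vector control transductions. Bulk expression profiling of every sample
then asks, per ORF: which genes did this overexpression move, and by how much?

The screening statistic implemented here works entirely on the log2 scale:

1. **Baseline** `b_g`: for each gene, the median of its merged log2 expression
   across *all* screened conditions (the pooled empty-vector control counts as
   one condition). A transcriptome-wide median is robust to the handful of
   conditions that genuinely move any one gene, so each condition's effect is
   measured against a stable reference without needing a dedicated control
   contrast per gene.
2. **Effect** `x(g, c) = profile(g, c) − b_g`: the log2 fold-induction of gene
   g under condition c. Effects are additive on the log2 scale and convert to
   fold changes as `FC = 2^x`, so an effect of 1 is exactly a 2-fold change
   and `x` and `−x` are reciprocal folds.
3. **Expected range of variation** `s_g`: the spread of a gene's effects
   across all conditions, estimated robustly (median absolute deviation
   × 1.4826, a consistent standard-deviation estimate under normality). The
   robustness matters: the very hits the screen wants to find are outliers of
   this distribution and must not inflate it.
4. **Z-score** `Z = x / s_g` and a four-way classification:
   `below_detection` when `b_g` falls under the detection floor; otherwise
   `within` (|Z| ≤ 2), `suggestive` (2 < |Z| ≤ 4), or `outside` (|Z| > 4).
5. **HIT calling**: a hit-tier call requires a detectable gene whose fold
   effect from the combined replicates exceeds 2 (|x| > 1) *and* whose
   expression lies outside the expected range (|Z| > 4); calls with
   2 < |Z| ≤ 4 form the suggestive tier. Direction is the sign of `x`.

Both criteria are necessary: the fold threshold discards statistically
reliable but tiny shifts in near-constant genes, and the Z criterion discards
large fold ratios in genes that swing widely across all conditions anyway.

## Parameters and defaults

| Parameter | Default | Units / meaning |
|---|---|---|
| `fold_threshold` | 2 | minimum fold effect; log2 threshold is `log2(2) = 1` |
| `z_hit` | 4 | \|Z\| bound of the "outside expected variation" (hit) class |
| `z_suggestive` | 2 | \|Z\| bound of the suggestive class |
| `detection_floor_log2` | 3 | minimum baseline log2 expression for detectability |
| `variance_estimator` | `"mad"` | per-gene scale estimator (`"sd"` available) |
| `variance_floor` | `NULL` | auto: 0.25 × median per-gene scale over detected genes |

Two points of genuine design freedom deserve explanation.

**The variance floor.** A gene whose effects happen to be near-constant across
conditions would get `s_g ≈ 0` and an unbounded Z, promoting negligible
fluctuations to hits. Every detected gene's scale is therefore floored at one
quarter of the median scale across detected genes (computed at run time from
the data, overridable with a fixed value). The factor 0.25 is deliberately
permissive — it only intervenes in the degenerate tail of the scale
distribution and leaves ordinary genes untouched.

**Where the variance is measured.** The expected range of variation is
estimated from condition-level (replicate-merged) effects, not from
individual replicates: the statistic asks whether a *condition's combined*
effect is unusual among conditions, and merged profiles are what the effect
itself is computed from. Replicate-level estimation can be emulated by
passing an unmerged matrix through the same functions.

**Detection** is assessed on the baseline, not on per-condition expression: a
gene silenced by one ORF but well-expressed at baseline remains a valid
down-regulated hit, while a gene below the floor everywhere yields no calls
in any condition. The floor of 3 on the log2 scale matches the expression
pre-filter used to select screen candidates.

**Boundary conventions.** Medians of even condition counts use the mean of
the middle two values; |Z| exactly at a class bound falls in the lower class
(|Z| = 2 is `within`, |Z| = 4 is `suggestive`); ordering ties in the per-ORF
hit-count table break alphabetically.

## Normalization and batch anchoring

Counts input is normalized to counts-per-million and transformed as
`log2(cpm + 1)` — the simplest defensible library-size correction; the
pseudocount is configurable and log2-scale input passes through untouched.
Quantile or TMM-style normalization is intentionally not applied by default;
users with strong composition effects should pre-normalize with their tool of
choice and supply log2 input.

Batches are merged by **control anchoring**: every batch contains empty-vector
control samples, so for each gene the batch's control mean is shifted onto the
global control mean. This removes additive per-gene batch offsets exactly,
never touches within-batch contrasts, and is idempotent. It assumes the batch
effect is additive on the log2 scale and shared by all samples of a batch —
the standard assumption for array/RNA-seq batch offsets — and relies on
controls being present in every batch, which the validator enforces.

Replicates are merged as unweighted means on the log2 scale, i.e. geometric
means of fold changes, so the reported effect is the one computed from the
combined replicates.

## The synthetic-screen generator

`simulate_screen()` emulates the screen design so every downstream stage is
verifiable without access to raw sequencing data: per-gene baselines drawn
once from `N(baseline_log2_mean, baseline_log2_sd)` (defaults 6 and 2, a
realistic log2 dynamic range for expressed genes); a `frac_undetectable`
subset (default 10%) forced below the detection floor; per-gene, per-batch
additive shifts (`batch_sd`, default 0.3 — batch effects are of the same
order as replicate noise, reflecting that replicate sets differ by infection
date, extraction and profiling batch); per-sample Gaussian log2 noise
(`noise_sd`, default 0.25); and `hits_per_orf` planted signed effects per ORF
with |log2 effect| uniform in `[effect_low, effect_high]` and Bernoulli(1/2)
signs, mirroring the observed mix of up- and down-regulated hits.

Defaults follow the verification conditions used throughout the tests —
5,000 genes, 10 ORFs in 3 batches, 3 replicate infections per ORF, 3 controls
per batch, 50 planted hits per ORF with |effect| in [1.5, 3] — while the
`analysis/` scripts run the full screen geometry (45 ORFs in three batches of
15, 12,000 genes). Planted effects are placed only on genes at least 1 log2
unit above the detection floor: a hit is by definition a detectable gene, so
truth placed on undetectable genes would be unrecoverable by construction
rather than by any property of the method. An optional counts mode
exponentiates the log2 means, applies multiplicative library-size factors
(lognormal, CV `libsize_cv`) and draws negative-binomial counts whose
log-scale dispersion matches `noise_sd`.

What the generator deliberately does **not** model: count-level mean–variance
coupling in log2 mode (noise is homoscedastic on the log2 scale),
gene–gene correlation, composition effects of very strong perturbations,
partial transduction or selection failures, and secondary (downstream-of-ORF)
regulatory cascades. Passing recovery tests therefore demonstrates that the
statistic and its implementation behave as specified under the stated noise
model — not that the thresholds are optimal for any particular real dataset.

## Concordance, shared hits and interval utilities

Replicate concordance is the Pearson correlation of two independently
processed replicate sets' log2 effect vectors over genes detected in both
(Spearman available). Under the default simulation conditions with a
strong-effect ORF (200 planted effects up to 3 log2 units, noise 0.2), the
two sets correlate at r > 0.9, the signature of a robust screen.

Shared-hit analysis compares hit sets between ORF pairs, by default
sign-aware (a gene counts only if both ORFs move it the same way). The exact
hypergeometric upper-tail probability is computed over the detected-gene
universe — only detectable genes can be hits, so a whole-genome universe
would overstate significance. This significance test is an addition of this
pipeline (the shared-impact observations it supports were originally made
descriptively), and outputs label it as such. The same machinery drives a
lightweight GMT gene-set overlap utility with Benjamini–Hochberg adjustment
across sets.

The promoter/TF utility answers the generic question "which factors have
binding evidence over *every* promoter window in a query set" with BED
0-based half-open interval semantics (abutting intervals do not overlap);
promoter window derivation from TSS annotations is the caller's
responsibility. The bundled `synthetic_*.bed` fixtures are constructed data
shaped like an ENCODE-style peak panel (12 factors, 7 qualifying), not real
ChIP-seq measurements.

## Numerical and degenerate-input behaviour

* A noise-free screen gives per-gene scales of zero for all genes; the
  automatic floor is then also zero, planted effects get infinite |Z| (called
  hits), and zero effects get undefined Z (never called). This degenerate
  limit is exercised in the tests.
* Validation fails loudly — duplicated ids, matrix/sheet mismatches, batches
  without controls, conditions spanning batches — before any statistic is
  computed; pipeline errors name the failing stage.
* All pipeline stages are deterministic; only `simulate_screen()` consumes
  randomness, governed entirely by its `seed` field. Verification problem
  sizes (5,000-gene screens, 20-seed null grids, 30 oracle matrices up to
  100 × 12) were chosen so the entire suite re-derives every expected value
  in about a minute.

## Known limitations

* Thresholds are conventions, not inferences: no p-values or FDR are attached
  to hit calls (by design — the two-tier |Z| classification *is* the method),
  so hit counts are not directly comparable between screens with different
  condition counts or noise levels.
* With few conditions (< ~6) the per-gene MAD is a coarse scale estimate and
  the median baseline itself absorbs part of any widespread effect; the
  pipeline requires ≥ 3 conditions and is intended for panels of tens of
  ORFs.
* Control anchoring corrects additive per-gene batch offsets only;
  multiplicative or rank-distorting batch artefacts require dedicated
  correction upstream.
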