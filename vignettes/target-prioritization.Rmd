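---
title: "Prioritizing cell-surface targets from RMS surfaceome proteomics"
author: "rmsurfaceome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing cell-surface targets from RMS surfaceome proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmsurfaceome)
```

## The problem

Rhabdomyosarcoma (RMS) is the most common pediatric soft-tissue sarcoma, and
patients with metastatic or fusion-positive disease need new treatment
options. Antibody-based therapies (antibody-drug conjugates, bispecifics,
CAR T-cells) require target proteins that sit on the tumor cell surface at
high copy number while being low or absent in normal tissue. This package
implements a complete, testable analysis pipeline for finding such targets
from label-free surfaceome proteomics of tumor cell lines and
patient-derived xenografts (PDXs) compared with normal control cultures
(fibroblasts and myoblasts), plus transcript-level and clinical validation
utilities.

The panel layout assumed throughout is six fusion-positive (FP-RMS) cell
lines, five fusion-negative (FN-RMS) cell lines, three PDXs and two control
cultures, each measured in triplicate (48 MS runs). Nothing in the code
requires those exact numbers — the design table drives everything — but
defaults, score grids and tests are built around this shape.

## From peptides to protein abundance (iTop3)

The input is a MaxQuant-style peptide × sample intensity table in which 0
means "not detected". Quantification proceeds in four steps.

**Normalization.** `normalize_peptides()` works on log2 intensities of the
detected values. The default `median_log2` equalizes per-sample medians — a
pure location correction that is idempotent and keeps fold changes
interpretable. A `vsn_arsinh` method is also provided: samples are rescaled
to a common median and transformed with the generalized log
`glog2(x) = log2(x + sqrt(x^2 + c^2)) - 1`, where `c` is the 10th percentile
of the rescaled detected intensities. This coincides with `log2` for
intense peptides and compresses variance near the detection floor, the
standard variance-stabilization behavior for MS intensities.

**Imputation.** Missingness in surface proteomics is left-censored: low
abundance peptides drop below the detection limit (missing not at random).
`impute_peptides()` therefore applies a two-stage rule on the log2 scale,
with replicate groups defined by the line (cell line / PDX / control):

1. *Down-shift stage.* If at most one replicate of a line detected the
   peptide, the missing replicates are drawn from
   `Normal(mu_s - 2.8 * sd_s, (0.3 * sd_s)^2)`, where `mu_s` and `sd_s` are
   the mean and SD of the detected values in that sample column. Near-total
   absence within a line is treated as censoring, and values are placed in
   the lower tail of that sample's intensity distribution
   (`P(draw < mu_s) = pnorm(2.8 / 0.3) ≈ 1`).
2. *MLE stage.* If two or more replicates were detected, the value is
   plainly missing at the peptide level, and the Gaussian maximum-likelihood
   conditional mean — the mean of the detected replicates of that peptide
   within the line — is filled in. Per-peptide Gaussian likelihood across a
   line's replicates was chosen because the replicate structure is the only
   grouping the model can defensibly exploit at n = 3.

The shift (2.8) and width (0.3) are in units of the sample SD; both must be
positive and are exposed in `run_config()`. Detected values are never
modified, and detection flags survive imputation so that downstream
detection calls use only raw evidence.

**Roll-up.** `itop3()` back-transforms to the linear scale and sums, per
protein and sample, the three most intense peptides (all of them when a
protein has fewer than three). Summation happens on the linear scale
because Top3-style abundance estimates approximate molar amounts through
ion-current sums, not through log averages.

**Detection and fold changes.** A protein is "detected in a line" when at
least 2 of 3 replicates carry signal for at least one of its peptides
(`min_replicates = 2`; a single stray replicate is not trusted). Group
fold changes are `log2(group mean iTop3 / control line mean iTop3)` for
each of the 3 tumor groups × 2 control lines. When the protein is not
detected in a control line this ratio is undefined on the data; the fixed
value 10 is substituted, which the scoring below treats as its own,
best-scoring category. A protein with zero tumor-group signal is dropped
from ranking rather than assigned an infinite negative fold change.

## Surface filtering

Quantified proteins are intersected with a curated surface-protein
annotation list ("List A" style, 2,886 entries in the published original)
to form the candidate set ("List C"); a larger membrane-protein list
("List B" style, 7,643 entries) is used only for enrichment summaries that
partition detected proteins into annotated-surface / predicted-membrane /
background. Matching is exact on upper-cased symbols — the package reports
mismatches rather than guessing aliases, because silent alias expansion is
a common source of irreproducible surfaceome counts.

## The scoring strategy

`score_protein()` applies a penalty-point grid in which **lower totals are
better**:

| component | grid |
|---|---|
| cell lines detected (of 14 tumor lines) | 14→0, 13→0.5, 12→1.5, 11→3, 10→5, 9→7.5, 8→10, 7→15, ≤6→30 |
| iTop3 mean (11 RMS cell lines) | ≥2.5e9→0 stepping to [5e6,1e7)→8; <5e6→9 |
| log2FC vs controls | 10→0, [6,10)→0.5, [5,6)→1, [4,5)→1.5, [3,4)→2, [2,3)→2.5, [1,2)→3, <1→3.5 |
| detected in controls | 0→0, 1→2.5, 2→5 |
| detected in PDXs | 3→0, 2→0.5, 1→1, 0→1.5 |
| specificity bonus | −3 if iTop3 mean >1e7 and undetected in both controls and ≥13 lines |

Design choices worth recording:

* **Cell-line count.** The grid runs to 14 and the bonus requires ≥13,
  which is only reachable when the three PDXs count toward the total; the
  count fed to the grid is therefore detections across all 14 tumor lines,
  while the abundance mean uses the 11 RMS cell lines only and PDXs enter
  separately through their bonus.
* **Bin boundaries.** Printed ranges abut ambiguously; all bins are
  lower-inclusive / upper-exclusive on the better-scoring side.
* **Fold-change aggregation.** Six comparisons (3 groups × 2 controls)
  collapse to one component by scoring each on the grid and averaging,
  which preserves the printed [0, 3.5] range; averaging raw fold changes
  first would let one extreme comparison dominate.
* **Below the last bin.** Abundance means under 5e6 continue the unit-step
  pattern with score 9 and are flagged (`below_last_bin`) in every report.
* **Ties.** Ranking is ascending by total, ties broken by descending iTop3
  mean (the more abundant candidate is the more actionable one), then by
  identifier for full determinism.

`score_mrna()` applies the transcript-level grid (normal-tissue FPKM 0–10,
tumor FPKM 0–15, expression in the five reference control tissues
brain/heart/kidney/liver/lung 0–1.25, tumor-vs-normal log2FC 0–10). The
summary statistics feeding it are the **maximum** FPKM across normal
tissues (conservative for safety) and the **median** across tumor samples;
a control tissue counts as expressing a gene at FPKM ≥ 5, reusing the
grid's own lowest bin edge. Proteomics and mRNA totals are kept as separate
columns; no combined formula is defined.

## Statistics

**Moderated t.** For every tumor line vs control line (triplicate vs
triplicate, 4 residual df), `eb_stats()` computes a moderated t in which
the per-protein pooled variance is shrunk toward an empirical-Bayes prior
fitted across proteins by moment matching on log variances
(`fit_eb_prior()`; the inverse-trigamma construction). The prior is fitted
on the filtered candidate set, per comparison. Selection
(`eb_select()`) averages fold changes and t statistics within each class
(FP-RMS, FN-RMS, PDX) and requires average log2FC ≥ 2 and average t ≥
2.132 — the 0.95 Student's t quantile at 4 df — in *all three* classes.
Both thresholds are configurable; a stricter per-comparison gate (minimum
log2FC 1 with BH-adjusted p ≤ 0.05) can be applied from the same output via
`adjust_bh()` / `volcano_table()`.

**Mixed model.** `fit_lmm()` evaluates each group against the controls
with `log2(iTop3) ~ group + (1 | line)`, REML, Satterthwaite degrees of
freedom — the line-level random intercept accounts for replicates being
repeated measurements of the same culture. When the random-effect variance
estimates to zero the model degenerates; the implementation then reports
the fixed-effects t-test and flags the fallback. BH adjustment is applied
within each group comparison. Because a full mixed-model pass is the most
expensive stage, `run_pipeline()` runs it on the EB-selected proteins by
default (`lmm_proteins = "all"` overrides).

**Clinical utilities.** `h_score()` is the linear IHC summary
`3·%strong + 2·%medium + 1·%weak` in [0, 300]. Kaplan–Meier, logrank and
univariate Cox (Efron ties) wrap the survival package behind the module's
interface. `best_cutoff()` scans every distinct expression value inside
the 10–90% quantile window and dichotomizes at the minimum logrank p.
The naive minimum p is reported because that is what the common online
tools report, but the scan is a multiple test: under the null it is
significant far more than 5% of the time (a property the test suite
demonstrates), so a permutation-adjusted p is available via
`adjust = "permutation"` and should be preferred for inference.

## What the synthetic module emulates — and what it does not

`truth_spec()` / `generate_panel()` produce panels with known ground
truth: log-normal peptide intensities (protein base means N(24, 2) on the
log2 scale, per-peptide offsets N(0, 1), per-line random effects N(0,
0.3), replicate noise N(0, 0.4)), logistic left-censoring (detection
probability `plogis((x - 18) / 1.5)`, monotone in intensity), and 20
planted surface targets among 1,000 proteins with log2 base 29.5 — iTop3
around 3e9, the top abundance bin — absent from the controls. These
magnitudes were chosen to sit inside the published score-grid ranges
(iTop3 bins spanning 1e6–2.5e9) and to mimic triplicate MS variability;
the companion generators emulate annotation lists (curated ⊆
comprehensive; real lists need not nest, and the filter never assumes it),
FPKM tables with the five reference control tissues, and survival cohorts
with exponential hazard `exp(beta · z)` on standardized log expression.

What passing tests on these panels shows: the pipeline's rules are
implemented correctly, planted effects of the stated size are recovered,
and the statistics are calibrated under the model that generated the data.
What it does not show: robustness to peptide-to-protein misassignment,
shared peptides, batch effects, non-Gaussian intensity noise, annotation
identifier mismatches, or real biological correlation structure — none of
which the generator simulates. Published dataset-level counts (e.g. a
specific number of filtered proteins) can only be reproduced from the
deposited tables, which must be supplied by the user
(`deposited_filter_counts()`).

## Numerical choices and problem sizes

* All stochastic stages take explicit seeds; a pipeline run is
  reproducible byte-for-byte from `run_config()`.
* Two-sided p-values are floored at the smallest positive double so that
  extreme statistics never report exactly zero.
* The EB prior fit falls back to `d0 = Inf` with the mean variance when
  the observed spread of log variances does not exceed its sampling
  expectation (degenerate prior), and never throws on short input.
* Test and acceptance simulations use panels of 1,000 proteins (about
  5,500 peptides × 48 samples), 10–20 seeds for recovery rates, 10,000
  draws for imputation calibration, and 200-rep simulations for mixed
  model and Cox recovery — sizes at which the Monte-Carlo error of each
  checked quantity is far below its test tolerance.

## Known limitations

* Identifier harmonization is deliberately out of scope: inputs must use
  one symbol namespace.
* The mixed model's Satterthwaite inference is approximate with only two
  control lines; strongly unbalanced designs should be interpreted with
  care.
* The best-cutoff naive p is biased by construction; use the permutation
  option for honest inference.
* Peptide-to-protein inference (razor peptides, isoform collapsing) is
  assumed done upstream.
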