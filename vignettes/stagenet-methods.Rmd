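---
title: "Methods: stage-specific hub-gene coexpression dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specific hub-gene coexpression dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagenet)
```

# The model

`stagenet` analyses how the star-shaped coexpression neighbourhood of a
single hub gene changes across disease phases. The phases are normal
precursor tissue (N) and pathologic tumour stages I–IV (S1–S4); samples
are assigned to phases by their TCGA barcode sample-type code
(tumour/normal) joined to the patient's pathologic stage.

## Coexpressed sets

Within one phase, gene *i* is coexpressed with the hub when the Spearman
rank correlation *r*ₛ between the two expression profiles lies strictly
in (0.3, 1] with a two-sided *P* < 0.05. Three points deserve emphasis:

* **One-sided positive rule.** The interval (0.3, 1] admits only positive
  correlations; a gene with *r*ₛ = −0.9 is *not* coexpressed. An
  `use_abs` flag exposes a magnitude-based variant but is off by default.
* **Strict inequalities at both thresholds.** A gene with *r*ₛ exactly
  0.3, or *P* exactly 0.05, is excluded. `rs_min = 1` therefore empties
  the set.
* **Degenerate genes.** Spearman correlation is undefined for a constant
  vector, so genes with zero within-phase variance are excluded (and
  counted in the table and the run log), not assigned *r*ₛ = 0.

The *P*-value uses the *t* approximation
*t* = *r*ₛ √((*n* − 2)/(1 − *r*ₛ²)) on *n* − 2 df, the behaviour of
common statistical packages at the group sizes of TCGA cohorts (tens to
hundreds of samples). At *r*ₛ = ±1 the *P*-value is floored at the
smallest representable positive double rather than reported as zero. The
exact permutation null is retained as a test oracle at *n* ≤ 8, where the
measured deviation of the approximation is below 0.1; both routes live in
the test suite, not the implementation.

No multiple-testing correction is applied inside the screening rule: the
selection criterion is the raw per-gene threshold, and the per-phase set
is the object of interest, not any individual gene's significance.
Correlations are computed over all genes passing the constant-gene
filter; no variance pre-filter is applied, and the constant-gene count is
logged so a run can be audited for how many genes the filter touched.

## Rewiring between phases

For an ordered phase pair *A* → *B* over the four transitions
(N, S1), (S1, S2), (S2, S3), (S3, S4):

* lost = *A* \ *B*, conserved = *A* ∩ *B*, acquired = *B* \ *A*;
* *J*(*A*, *B*) = |*A* ∩ *B*| / |*A* ∪ *B*|, defined as 0 when both sets
  are empty;
* loss percentage = 100·|lost|/|*A*| (relative to the **source** set) and
  gain percentage = 100·|acquired|/|*B*| (relative to the
  **destination** set).

The loss/gain denominators are the only pair of definitions under which
the published KIRC worked example is internally consistent (stage I/II
sets of 280 and 1173 genes, 82.09% gain, conserved ≈ 210, Jaccard ≈ 17%);
the corresponding published KIPAN stage III/IV percentages cannot be
reconciled with the stage IV set count under any single convention we
tried, and are treated as an erratum rather than reverse-engineered.
Percentages are reported at two decimals and Jaccard matrices at integer
percent, both round-half-to-even (R's `round`).

Gene sets are compared by Entrez identifier, falling back to the symbol
only when the numeric id is unknown: symbols are aliased and unstable
across annotation releases, numeric ids are not.

## Consistency and the diagnostic/prognostic screen

A gene is *consistent* in a cohort when it appears in the coexpressed set
of every tumour stage S1–S4 (the normal phase is deliberately excluded:
the question is persistence through disease, not presence in health).
Consistent sets intersected across cohorts give the common candidates.

Each candidate is screened on two independent arms, both at α = 0.05:

* **Diagnostic.** Two-sided Mann–Whitney *U* of expression in pooled
  tumour samples (all stages) versus normal samples; the gene must be
  significantly *higher* in tumour. Pooling matches the single
  tumour-vs-normal decision the analysis needs; a per-stage comparison is
  available through `mannWhitney` directly.
* **Prognostic.** Tumour samples with usable survival records are split
  at the 25th/75th expression percentiles: the high arm is strictly above
  the 75th, the low arm strictly below the 25th, the middle half is
  discarded and boundary ties enter neither arm. Kaplan–Meier curves are
  fitted per arm and compared by the two-group log-rank (Mantel–Cox)
  test; the gene must be significant *and* the high arm must be the worse
  survivor.

"Worse" is operationalised as the smaller restricted mean survival time
up to the shorter arm's last follow-up — a direction label robust to
crossing tails, needed because the verdict requires high expression to
predict poor survival, not merely different survival.

Percentiles use linear interpolation (R `quantile` type 7), the standard
convention; on values 1..8 this puts the quartiles at 2.75 and 6.25.
Quartiles are computed over tumour samples with usable survival records
only, since the split exists solely to feed the survival comparison —
normal samples have no survival semantics in this design. Unscreenable
genes (no normals, degenerate split, too few survival records) are
carried with `passes = FALSE` and a reason code rather than dropped.

The Mann–Whitney implementation uses mid-ranks for ties; mode `auto`
enumerates the exact null when *n*₁·*n*₂ ≤ 400 with no ties and otherwise
uses the normal approximation with tie and continuity correction (the two
agree within |ΔP| ≤ 0.01 on tie-free inputs in that range). Fully tied
data return *P* = 1: they carry no evidence. The mode actually used is
returned with every result.

## Methylation

Promoter methylation is compared per gene between phase pairs by the same
two-sided Mann–Whitney on β-values, with medians reported. β-values are
validated into [0, 1] on input; the Firehose min-expression-correlation
preprocessing upstream already maps each gene to one probe, so the reader
treats the matrix as one β row per gene and performs no probe selection.

# File-format decisions

The Firehose dialect readers strip the second "datatype tag" header row
when present, accept `?` as an unknown symbol (`?|100130426` keeps its
Entrez id), and reject duplicate sample barcodes. Missing expression
values default to dropping the gene (`drop_gene`), because rank
correlation over partially missing rows is ill-defined and no imputation
is part of the procedure; `impute_zero` exists for explicitly sparse
inputs. Duplicate gene rows keep the row with the larger total signal,
ties broken by file order — a deterministic, documented tie-break.
Clinical tables are joined to samples by the 12-character patient prefix;
all of a patient's samples inherit the patient's stage and survival
record, and multiple tumour samples per patient are retained (collapsing
them is a cohort-design choice the pipeline does not impose; the run log
records that none was applied). Stage sub-letters (IA/IB/…) collapse to
the parent stage, as the analysis works at stage resolution; unparseable
stage strings map to `unknown` and such samples join no phase group.

# The synthetic-cohort generator

The generator exists so that every downstream stage can be tested against
known truth. Its construction mirrors the statistical structure the
analysis assumes:

* **Planted coexpression.** Per phase, a standard-normal latent hub
  signal *h* is drawn per sample; a planted gene's latent value is
  *a*·*h* + (1 − *a*)·ε with loading *a* (`coexpr_strength`) and
  independent ε. All latent values pass through exp(·), a strictly
  monotone map to a non-negative RSEM-like scale — chosen precisely
  because Spearman correlation is invariant under it, so the planted
  correlation survives the transform and remains the controllable truth.
* **Expression shifts.** Core genes and the hub gain a constant log-scale
  shift in tumour phases, which changes tumour-vs-normal location without
  touching within-phase ranks.
* **Methylation.** β-values are clamped normal draws: the hub's promoter
  mean is phase-specific (hypomethylated in tumour phases by default),
  other genes centre at 0.5.
* **Survival.** Tumour survival is exponential; samples strictly above
  the 75th percentile of the designated prognostic gene's tumour
  expression have their hazard multiplied by `hazard_ratio_high`.
  Censoring is an independent exponential calibrated so that the
  marginal censored fraction is `censor_rate` under the baseline hazard
  — the simplest model in which the quartile split has a known
  directional effect.
* **Substreams.** The global seed expands into one substream per
  expression phase plus one each for methylation and survival, with
  gene-major noise draws; enlarging the gene panel therefore leaves
  survival (and earlier genes' values) bit-identical, which the tests
  assert.

## Reference conditions

The defaults are the package's reference simulation, fixed once: 2000
genes plus the hub, 100 samples per phase, loading 0.95, per-phase
planted modules of 100–200 genes sharing a 15-gene all-stage core whose
first four genes form the cross-cohort common core (a second layout
variant swaps the eleven non-common core genes, so two cohorts share
exactly four consistent genes), tumour log-shift 1.0, β means 0.60 (N) vs
0.30–0.40 (S1–S4) with sd 0.05, hazard ratio 3, 20% censoring, baseline
hazard log 2/1000 per day (median ~1000 days). Planted modules of ~100+
genes keep the expected handful of false positives (the one-sided
tail beyond *r*ₛ = 0.3 at *n* = 100 is ~0.1% of null genes) a small
fraction of each recovered set. These sizes are what a bulk TCGA-scale
cohort plausibly offers a single-hub analysis, and they are the
conditions under which the recovery tests run (ten seeds; sensitivity,
contamination, per-phase Jaccard error, exact common-core recovery, and
null false-positive and screen-pass rates).

## What the generator does not emulate

Negative-binomial count noise and library-size effects, batch effects,
copy-number structure, correlated gene-gene modules independent of the
hub, non-exponential hazards, and informative censoring. Passing recovery
tests therefore demonstrates that the pipeline's inference is correct
when its assumptions hold — not that the thresholds are optimal for real
RNA-seq noise. The unit suite and smaller property tests run on scaled
configurations (300–600 genes, 20–40 samples per phase) for speed; the
recovery and determinism checks use the reference conditions above.

# Known limitations

* The hub-centred star ignores gene–gene edges among the coexpressed set;
  no WGCNA-style module detection, partial correlation or edge weighting
  is attempted.
* The prognostic screen is a two-arm quartile contrast, not a Cox model;
  hazard-ratio estimates and covariate adjustment are out of scope.
* Jaccard overlap significance (e.g. hypergeometric) is not computed; the
  index is descriptive.
* Pathway enrichment of the lost/conserved/acquired lists requires an
  external annotation database; the pipeline writes one-id-per-line gene
  lists suitable as input to external enrichment tools instead.
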