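# stagenet

Stage-specific hub-gene coexpression network dynamics.

## The problem

In bulk tumour transcriptomics, the set of genes coexpressed with a hub
gene (for example *Myc* in renal cell carcinoma) is not fixed: it rewires
as the disease progresses from normal precursor tissue through pathologic
stages I–IV. `stagenet` implements that analysis as a tested pipeline:

1. **Per-stage coexpressed sets.** Within each sample group *g* ∈ {N, S1,
   S2, S3, S4}, a gene *i* belongs to the hub's coexpressed set when its
   Spearman rank correlation with the hub satisfies *r*ₛ ∈ (0.3, 1] with
   *P* < 0.05 (two-sided, *t* approximation on *n* − 2 df). Only positive
   correlations qualify; genes constant within the group are excluded.
2. **Rewiring across phases.** For consecutive phase sets *A* → *B*
   ((N, S1), (S1, S2), (S2, S3), (S3, S4)): lost = *A* \ *B*, conserved =
   *A* ∩ *B*, acquired = *B* \ *A*, with similarity measured by the
   Jaccard index *J*(*A*, *B*) = |*A* ∩ *B*| / |*A* ∪ *B*|. Loss
   percentages are relative to |*A*|, gain percentages to |*B*|.
3. **Consistency and biomarker screening.** Genes in every stage set
   S1–S4 are "consistent"; intersecting consistent sets across cohorts
   gives common candidates. Each candidate is screened for diagnostic
   value (two-sided Mann–Whitney *U*, pooled tumour vs normal, tumour
   side higher) and prognostic value (Kaplan–Meier on the quartile split
   — samples strictly above the 75th / below the 25th expression
   percentile — with the log-rank (Mantel–Cox) test, high arm worse).
4. **Promoter methylation.** Stage-wise Mann–Whitney comparisons of
   β-values (methylated / total allele intensity, in [0, 1]).

Inputs are Broad GDAC Firehose-style Level-3 tables: RSEM-normalized
expression TSVs keyed by `SYMBOL|ENTREZ`, methylation-preprocess β-value
TSVs, and Clinical_Pick_Tier1 tables (pathologic stage, vital status,
follow-up). Tumour/normal status comes from TCGA barcode sample-type
codes (01–09 tumour, 10–19 normal). A seeded synthetic-cohort generator
with planted modules, expression shifts, methylation differences and
survival effects makes the whole pipeline testable offline.

## Worked example

```r
library(stagenet)

cfg <- synthConfig(seed = 42)          # 2000 genes + hub, 100 samples/group
co  <- simulateCohort(cfg)
prof <- stageProfile(co, "MYC|4609")   # coexpressed set per group
profileCounts(list(SYNTH = prof))
#>         N  S1  S2  S3  S4
#> SYNTH 202 102 154 122 111

transitionReport(phaseSeries(prof))
#>       phase n_from n_to n_lost n_conserved n_acquired pct_lost pct_acquired jaccard_pct
#> N.S1   N/S1    202  102    187          15         87    92.57        85.29           5
#> S1.S2 S1/S2    102  154     47          55         99    46.08        64.29          27
#> S2.S3 S2/S3    154  122     89          65         57    57.79        46.72          31
#> S3.S4 S3/S4    122  111     72          50         61    59.02        54.95          27

cons <- consistentGenes(prof)          # in all four stage sets
length(cons)
#> [1] 15

head(screenGenes(co, cons)[, c("gene", "diag_p", "logrank_p", "worse_group", "passes")], 2)
#>         gene       diag_p    logrank_p worse_group passes
#> 1 G1|100001 1.295343e-21 2.240519e-11        high   TRUE
#> 2 G2|100002 3.833397e-22 1.089424e-11        high   TRUE
```

The counts recover the planted layout (per-stage modules of 100–200
genes, sensitivity ~1, contamination ~2%): the coexpressed set collapses
from normal to stage I (Jaccard 5%) and stays moderately similar between
consecutive tumour stages (~27–31%). The 15 consistent genes are the
planted all-stage core; they pass the screen because they are
tumour-shifted and correlated with the hazard-linked prognostic gene.

The full two-cohort pipeline runs from a YAML config:

```r
runPipeline(system.file("extdata", "synth_config.yaml", package = "stagenet"),
            "out/", seed = 1)
```

writing per-group coexpression TSVs, transition reports, consistent and
cross-cohort-common gene lists, screen reports, methylation comparisons,
`summary.json` and a `run.log` of every silent analysis decision. The
same script-level interface is in `inst/scripts/stagenet.R`
(`simulate` / `run-all` subcommands).

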