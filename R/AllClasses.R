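#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

## Canonical sample-group labels: normal precursor tissue plus tumour
## stages I-IV. Order matters: phase transitions walk consecutive pairs.
STAGE_GROUPS <- c("N", "S1", "S2", "S3", "S4")
TUMOUR_STAGES <- c("S1", "S2", "S3", "S4")

#' StageCohort: expression, methylation and sample annotations for one cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying an RSEM-normalized
#' expression assay (`"rsem"`, genes x samples) with per-gene `symbol` /
#' `entrez` row data and per-sample annotations in `colData` (`barcode`,
#' `cohort`, `tissue`, `stage`, `time_days`, `event`, `surv_ok`), plus a
#' promoter beta-value matrix and, for simulated cohorts, the generating
#' configuration as ground truth.
#'
#' Sample groups are `"N"` (normal tissue) and tumour stages `"S1"`-`"S4"`;
#' normals always carry stage `"N"`, tumour samples a stage or `"unknown"`.
#'
#' @slot methylation numeric matrix of beta-values in \[0, 1\] (possibly
#'   0-row), columns a subset of the expression samples.
#' @slot truth list; the synthetic-generator configuration for simulated
#'   cohorts, empty for cohorts read from files.
#'
#' @aliases StageCohort
#' @export
setClass("StageCohort",
  contains = "SummarizedExperiment",
  representation(methylation = "matrix", truth = "list")
)

setValidity("StageCohort", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("barcode", "cohort", "tissue", "stage", "time_days", "event", "surv_ok")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(setdiff(need, colnames(cd)), collapse = ", ")))
  } else {
    if (!all(cd$tissue %in% c("normal", "tumour")))
      msg <- c(msg, "tissue must be 'normal' or 'tumour'")
    if (any(cd$tissue == "normal" & cd$stage != "N"))
      msg <- c(msg, "normal samples must have stage 'N'")
    if (any(cd$tissue == "tumour" & !cd$stage %in% c(TUMOUR_STAGES, "unknown")))
      msg <- c(msg, "tumour samples must have stage S1-S4 or 'unknown'")
    if (any(stats::na.omit(cd$time_days) < 0))
      msg <- c(msg, "time_days must be non-negative")
  }
  rd <- rowData(object)
  if (!all(c("symbol", "entrez") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain symbol and entrez")
  ex <- assay(object, "rsem")
  if (any(ex < 0, na.rm = TRUE))
    msg <- c(msg, "expression values must be non-negative")
  me <- object@methylation
  if (length(me) && (any(me < 0, na.rm = TRUE) || any(me > 1, na.rm = TRUE)))
    msg <- c(msg, "beta-values must lie in [0, 1]")
  if (length(me) && nrow(me) > 0 && !all(colnames(me) %in% colnames(ex)))
    msg <- c(msg, "methylation samples must be a subset of expression samples")
  if (anyDuplicated(colnames(ex)))
    msg <- c(msg, "duplicate sample barcodes")
  if (length(msg)) msg else TRUE
})

#' CoexpressionTable: genes coexpressed with the hub in one sample group
#'
#' Per-gene Spearman statistics against the hub gene within one
#' (cohort, group) cell, together with the thresholded gene set
#' (rs strictly above `rs_min`, at most 1, and p strictly below `p_max`;
#' the hub itself and constant genes are excluded).
#'
#' @slot cohort single cohort label.
#' @slot group one of N, S1..S4.
#' @slot hub display id ("SYMBOL|ENTREZ") of the hub gene.
#' @slot results data.frame with columns gene, symbol, entrez, rs, p, in_set.
#' @slot params list with rs_min, p_max, use_abs, n_samples.
#' @slot n_constant number of genes excluded for zero within-group variance.
#' @export
setClass("CoexpressionTable",
  representation(cohort = "character", group = "character", hub = "character",
                 results = "data.frame", params = "list", n_constant = "integer")
)

#' TransitionSummary: rewiring between two phase gene sets
#'
#' Classifies genes across an ordered phase pair A -> B into lost (A \\ B),
#' conserved (A intersect B) and acquired (B \\ A), with the Jaccard index
#' and the loss/gain percentages (loss relative to |A|, gain relative to
#' |B|, conservation relative to |A union B|), percentages rounded
#' half-to-even to 2 decimals.
#'
#' @slot from_group,to_group phase labels.
#' @slot lost,conserved,acquired character vectors of gene keys.
#' @slot jaccard Jaccard index in \[0, 1\].
#' @slot pct_lost,pct_acquired,pct_conserved_of_union percentages.
#' @export
setClass("TransitionSummary",
  representation(from_group = "character", to_group = "character",
                 lost = "character", conserved = "character",
                 acquired = "character", jaccard = "numeric",
                 pct_lost = "numeric", pct_acquired = "numeric",
                 pct_conserved_of_union = "numeric")
)

setValidity("TransitionSummary", function(object) {
  msg <- character()
  if (length(intersect(object@lost, object@acquired)))
    msg <- c(msg, "lost and acquired must be disjoint")
  if (object@jaccard < 0 || object@jaccard > 1)
    msg <- c(msg, "jaccard must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' @slot times increasing event times.
#' @slot surv survival probabilities, non-increasing, in \[0, 1\].
#' @slot at_risk number at risk just before each time.
#' @slot n_events number of deaths at each time.
#' @slot n number of subjects.
#' @export
setClass("KMCurve",
  representation(times = "numeric", surv = "numeric",
                 at_risk = "integer", n_events = "integer", n = "integer")
)

setValidity("KMCurve", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE)) msg <- c(msg, "times must be strictly increasing")
  if (length(object@surv) && (any(object@surv < 0) || any(object@surv > 1)))
    msg <- c(msg, "survival must lie in [0, 1]")
  if (length(object@surv) > 1 && any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' GeneScreen: diagnostic and prognostic screen result for one gene
#'
#' Passing requires all of: tumour-vs-normal Mann-Whitney p below alpha with
#' tumour expression higher, and quartile-split log-rank p below alpha with
#' the high-expression arm showing worse survival.
#'
#' @slot gene display id of the screened gene.
#' @slot diag_p,diag_direction Mann-Whitney p and direction
#'   ("tumour_higher", "normal_higher", "none").
#' @slot km_high,km_low Kaplan-Meier curves for the arms (may be empty).
#' @slot logrank_p log-rank p-value.
#' @slot worse_group "high", "low" or "none".
#' @slot passes logical screen verdict.
#' @slot reason reason code when unscreenable ("" otherwise).
#' @export
setClass("GeneScreen",
  representation(gene = "character", diag_p = "numeric", diag_direction = "character",
                 km_high = "KMCurve", km_low = "KMCurve", logrank_p = "numeric",
                 worse_group = "character", passes = "logical", reason = "character")
)
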