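#' Genes consistently coexpressed with the hub across all tumour stages
#'
#' Intersection of the thresholded gene sets of stages S1..S4 (the normal
#' group is excluded from the intersection). All four stages must be
#' present.
#'
#' @param profile named list of [CoexpressionTable-class] from
#'   [stageProfile()].
#' @return character vector of gene keys.
#' @export
consistentGenes <- function(profile) {
  missing <- setdiff(TUMOUR_STAGES, names(profile))
  if (length(missing))
    stop("missing stage(s) for consistency: ", paste(missing, collapse = ", "))
  Reduce(intersect, lapply(profile[TUMOUR_STAGES], function(x) {
    if (is(x, "CoexpressionTable")) geneSet(x) else x
  }))
}

#' Genes consistent across every cohort
#'
#' Intersection of per-cohort consistent sets.
#'
#' @param consistent named list (by cohort) of character gene-key vectors
#'   (e.g. outputs of [consistentGenes()]).
#' @return character vector of gene keys common to all cohorts.
#' @export
crossCohortConsistent <- function(consistent) {
  if (length(consistent) < 2) stop("need at least 2 cohorts")
  Reduce(intersect, consistent)
}

#' Quartile split of expression values for survival grouping
#'
#' The high arm holds samples strictly above the 75th percentile, the low
#' arm samples strictly below the 25th percentile; the middle half is
#' discarded and samples tied exactly at a boundary enter neither arm.
#' Percentiles use linear interpolation (R quantile type 7).
#'
#' @param values named numeric vector (names = sample barcodes) over the
#'   samples eligible for survival analysis.
#' @return list with `high` and `low` (character vectors of names),
#'   `q25`, `q75`, and `usable` (both arms have >= 2 samples).
#' @export
quartileSplit <- function(values) {
  if (length(values) < 8) stop("need >= 8 samples for a quartile split")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  high <- names(values)[values > q[2]]
  low <- names(values)[values < q[1]]
  list(high = high, low = low, q25 = q[1], q75 = q[2],
       usable = length(high) >= 2 && length(low) >= 2)
}

#' Diagnostic and prognostic screen of one gene
#'
#' Diagnostic arm: two-sided Mann-Whitney of the gene's expression in all
#' tumour samples (stages pooled) against normal samples. Prognostic arm:
#' quartile split of expression over tumour samples with usable survival
#' records, Kaplan-Meier in each arm, two-group log-rank. The gene passes
#' when the tumour side is significantly higher (p < alpha) and the
#' high-expression arm has significantly worse survival (log-rank
#' p < alpha with the high arm's restricted mean lower).
#'
#' Genes that cannot be screened (no normals, degenerate split, too few
#' survival records) are returned with `passes = FALSE` and a reason code.
#'
#' @param cohort a [StageCohort-class].
#' @param gene gene identifier.
#' @param alpha significance level for both arms (default 0.05).
#' @return a [GeneScreen-class].
#' @export
screenGene <- function(cohort, gene, alpha = 0.05) {
  gi <- geneRow(cohort, gene)
  info <- sampleInfo(cohort)
  expr <- expressionMatrix(cohort)[gi, ]
  emptyKM <- new("KMCurve", times = numeric(0), surv = numeric(0),
                 at_risk = integer(0), n_events = integer(0), n = 0L)
  fail <- function(reason, diag_p = NA_real_, diag_dir = "none") {
    new("GeneScreen", gene = rownames(cohort)[gi], diag_p = diag_p,
        diag_direction = diag_dir, km_high = emptyKM, km_low = emptyKM,
        logrank_p = NA_real_, worse_group = "none", passes = FALSE,
        reason = reason)
  }
  tum <- info$tissue == "tumour"
  nor <- info$tissue == "normal"
  if (sum(nor) < 2 || sum(tum) < 2) return(fail("insufficient_normal_or_tumour"))
  mw <- mannWhitney(expr[tum], expr[nor])
  diag_dir <- switch(mw$direction, group1_higher = "tumour_higher",
                     group2_higher = "normal_higher", "none")
  ## prognostic arm: quartiles over tumour samples with usable survival
  sv <- tum & info$surv_ok
  if (sum(sv) < 8) return(fail("insufficient_survival", mw$p_value, diag_dir))
  vals <- expr[sv]
  names(vals) <- info$barcode[sv]
  qs <- quartileSplit(vals)
  if (!qs$usable) return(fail("degenerate_quartile_split", mw$p_value, diag_dir))
  svinfo <- info[sv, ]
  hi <- svinfo[svinfo$barcode %in% qs$high, ]
  lo <- svinfo[svinfo$barcode %in% qs$low, ]
  lr <- logrankTest(hi$time_days, hi$event, lo$time_days, lo$event)
  worse <- switch(lr$direction, group1_worse = "high", group2_worse = "low", "none")
  passes <- mw$p_value < alpha && diag_dir == "tumour_higher" &&
    lr$p_value < alpha && worse == "high"
  new("GeneScreen", gene = rownames(cohort)[gi], diag_p = mw$p_value,
      diag_direction = diag_dir,
      km_high = kmFit(hi$time_days, hi$event),
      km_low = kmFit(lo$time_days, lo$event),
      logrank_p = lr$p_value, worse_group = worse, passes = passes,
      reason = "")
}

setMethod("show", "GeneScreen", function(object) {
  cat("GeneScreen ", object@gene, ": diag p=", signif(object@diag_p, 3),
      " (", object@diag_direction, "), log-rank p=",
      signif(object@logrank_p, 3), " (worse=", object@worse_group,
      ") -> ", if (object@passes) "PASS" else paste0("fail",
        if (nzchar(object@reason)) paste0(" [", object@reason, "]") else ""),
      "\n", sep = "")
})

#' Screen a list of candidate genes
#'
#' Runs [screenGene()] over candidates and tabulates the results.
#'
#' @param cohort a [StageCohort-class].
#' @param genes character vector of gene identifiers (keys, symbols or
#'   full ids).
#' @param alpha significance level.
#' @return data.frame: gene, diag_p, diag_direction, logrank_p,
#'   worse_group, passes, reason.
#' @export
screenGenes <- function(cohort, genes, alpha = 0.05) {
  rows <- lapply(genes, function(g) {
    s <- screenGene(cohort, g, alpha = alpha)
    data.frame(gene = s@gene, diag_p = s@diag_p,
               diag_direction = s@diag_direction, logrank_p = s@logrank_p,
               worse_group = s@worse_group, passes = s@passes,
               reason = s@reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percentage of differentially expressed genes
#'
#' `100 * de_count / total` at 2 decimals, round-half-to-even.
#'
#' @param de_count number of differentially expressed genes.
#' @param total total genes considered (> 0).
#' @return percentage.
#' @examples
#' percentDE(40, 104)  # 38.46
#' @export
percentDE <- function(de_count, total) {
  stopifnot(length(de_count) == 1, length(total) == 1)
  if (total <= 0) stop("total must be positive")
  if (de_count < 0 || de_count > total) stop("de_count must lie in [0, total]")
  round(100 * de_count / total, 2)
}

#' Differential-expression summary of a gene set
#'
#' Counts how many of the given genes are significantly higher in pooled
#' tumour versus normal samples (two-sided Mann-Whitney, p < alpha, tumour
#' side higher), the filter applied to acquired-gene sets.
#'
#' @param cohort a [StageCohort-class].
#' @param genes character vector of gene identifiers.
#' @param alpha significance level.
#' @return list with `n_de`, `n_total`, `pct` (via [percentDE()]) and the
#'   per-gene logical vector `de`.
#' @export
percentDEGenes <- function(cohort, genes, alpha = 0.05) {
  info <- sampleInfo(cohort)
  tum <- info$tissue == "tumour"; nor <- info$tissue == "normal"
  mat <- expressionMatrix(cohort)
  de <- vapply(genes, function(g) {
    v <- mat[geneRow(cohort, g), ]
    mw <- mannWhitney(v[tum], v[nor])
    mw$p_value < alpha && mw$direction == "group1_higher"
  }, logical(1))
  list(n_de = sum(de), n_total = length(genes),
       pct = if (length(genes)) percentDE(sum(de), length(genes)) else 0,
       de = de)
}
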