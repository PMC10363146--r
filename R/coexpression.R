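#' Genes coexpressed with the hub in one sample group
#'
#' Within the samples of one (cohort, group) cell, computes the tie-aware
#' Spearman correlation of every other gene against the hub gene and
#' thresholds it with strict inequalities: a gene enters the coexpressed
#' set when `rs_min < rs <= 1` and `p < p_max` (defaults rs_min = 0.3,
#' p_max = 0.05, positive correlations only). Genes constant within the
#' group are excluded (Spearman is undefined on them) and counted.
#'
#' The per-gene statistics match [spearmanTest()]; the computation is
#' vectorized (mid-ranks once, then one correlation against the hub rank
#' vector).
#'
#' @param cohort a [StageCohort-class].
#' @param group sample group, one of `"N"`, `"S1"`..`"S4"`.
#' @param hub hub gene identifier (any form accepted by the cohort).
#' @param rs_min correlation threshold, in \[0, 1).
#' @param p_max p-value threshold.
#' @param use_abs if TRUE threshold on |rs| instead of rs (off by default:
#'   the selection rule is one-sided positive).
#' @return a [CoexpressionTable-class].
#' @export
coexpressedSet <- function(cohort, group, hub, rs_min = 0.3, p_max = 0.05,
                           use_abs = FALSE) {
  stopifnot(rs_min >= 0, rs_min < 1, p_max > 0, p_max <= 1)
  samples <- groupSamples(cohort, group)
  if (length(samples) < 4) stop("group ", group, " has fewer than 4 samples")
  hi <- geneRow(cohort, hub)
  mat <- expressionMatrix(cohort)[, samples, drop = FALSE]
  hubv <- mat[hi, ]
  if (length(unique(hubv)) < 2) stop("hub gene is constant in group ", group)
  others <- setdiff(seq_len(nrow(mat)), hi)
  sub <- mat[others, , drop = FALSE]
  constant <- apply(sub, 1, function(v) length(unique(v)) < 2)
  idx <- others[!constant]
  n <- length(samples)
  if (length(idx)) {
    rmat <- apply(mat[idx, , drop = FALSE], 1, rank)  # samples x genes
    rs <- as.vector(stats::cor(rank(hubv), rmat))
    p <- spearmanPvalue(rs, n)
  } else {
    rs <- numeric(0); p <- numeric(0)
  }
  rd <- rowData(cohort)
  crit <- if (use_abs) abs(rs) else rs
  in_set <- crit > rs_min & crit <= 1 & p < p_max
  results <- data.frame(
    gene = rd$key[idx], symbol = rd$symbol[idx], entrez = rd$entrez[idx],
    rs = rs, p = p, in_set = in_set, stringsAsFactors = FALSE
  )
  new("CoexpressionTable",
      cohort = cohortName(cohort), group = group,
      hub = rownames(cohort)[hi], results = results,
      params = list(rs_min = rs_min, p_max = p_max, use_abs = use_abs,
                    n_samples = n),
      n_constant = sum(constant))
}

#' @rdname geneSet
#' @export
setMethod("geneSet", "CoexpressionTable", function(x) {
  x@results$gene[x@results$in_set]
})

#' @rdname CoexpressionTable-class
#' @export
setMethod("coexResults", "CoexpressionTable", function(x) x@results)

setMethod("show", "CoexpressionTable", function(object) {
  cat("CoexpressionTable ", object@cohort, "/", object@group,
      " hub=", object@hub, ": ", sum(object@results$in_set), " of ",
      nrow(object@results), " genes in set (rs > ", object@params$rs_min,
      ", p < ", object@params$p_max, "; ", object@n_constant,
      " constant excluded)\n", sep = "")
})

#' Stage profile: one coexpression table per available group
#'
#' Builds [coexpressedSet()] tables for every group (N, S1..S4) that has
#' enough samples; groups absent from the cohort (or with fewer than 4
#' samples) are skipped with a warning and omitted from the result.
#'
#' @inheritParams coexpressedSet
#' @param groups groups to attempt, default all five.
#' @return named list of [CoexpressionTable-class] objects.
#' @export
stageProfile <- function(cohort, hub, rs_min = 0.3, p_max = 0.05,
                         use_abs = FALSE, groups = STAGE_GROUPS) {
  out <- list()
  for (g in groups) {
    if (length(groupSamples(cohort, g)) < 4) {
      warning("group ", g, " absent or too small in cohort ",
              cohortName(cohort), "; skipped")
      next
    }
    out[[g]] <- coexpressedSet(cohort, g, hub, rs_min = rs_min,
                               p_max = p_max, use_abs = use_abs)
  }
  out
}

#' Coexpressed-gene counts in a groups-by-cohorts layout
#'
#' @param profiles named list (by cohort) of stage profiles from
#'   [stageProfile()].
#' @return integer matrix, rows = cohorts, columns = groups; NA where a
#'   group is absent.
#' @export
profileCounts <- function(profiles) {
  m <- matrix(NA_integer_, nrow = length(profiles), ncol = length(STAGE_GROUPS),
              dimnames = list(names(profiles), STAGE_GROUPS))
  for (co in names(profiles)) {
    for (g in names(profiles[[co]])) {
      m[co, g] <- length(geneSet(profiles[[co]][[g]]))
    }
  }
  m
}

#' Write a coexpression table as TSV
#'
#' Columns: gene key, symbol, entrez, rs, p, in_set.
#'
#' @param table a [CoexpressionTable-class].
#' @param path output path.
#' @export
writeCoexpressionTable <- function(table, path) {
  utils::write.table(coexResults(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
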