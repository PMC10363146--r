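#' Compare promoter methylation of a gene between two sample groups
#'
#' Two-sided Mann-Whitney on the beta-values of one gene between two
#' groups (e.g. normal vs stage I), with group medians. Significance is
#' assessed at p < 0.05 by convention; the p-value itself is returned.
#'
#' @param cohort a [StageCohort-class] with a methylation matrix.
#' @param gene gene identifier (matched against the methylation rownames
#'   the same way expression rows are matched).
#' @param pair character vector of two group labels, e.g. `c("N", "S1")`.
#' @param alpha significance level used for the `significant` flag.
#' @return list with `gene`, `pair`, `medians` (named per group),
#'   `statistic`, `p_value`, `direction` (`"first_higher"`,
#'   `"second_higher"`, `"none"`), `significant`.
#' @export
compareMethylation <- function(cohort, gene, pair, alpha = 0.05) {
  stopifnot(length(pair) == 2, all(pair %in% STAGE_GROUPS))
  meth <- methylationMatrix(cohort)
  if (!length(meth) || nrow(meth) == 0) stop("cohort has no methylation data")
  if (any(meth < 0, na.rm = TRUE) || any(meth > 1, na.rm = TRUE))
    stop("validation error: beta-values outside [0, 1]")
  ids <- parseGeneId(rownames(meth))
  keys <- geneKey(ids$symbol, ids$entrez)
  i <- which(rownames(meth) == gene | keys == gene | ids$symbol == gene |
               ids$entrez == suppressWarnings(as.integer(gene)))
  if (!length(i)) stop("gene not found in methylation matrix: ", gene)
  i <- i[1]
  info <- sampleInfo(cohort)
  pick <- function(g) {
    bc <- intersect(info$barcode[info$stage == g], colnames(meth))
    if (length(bc) < 4) stop("group ", g, " absent or too small in methylation data")
    v <- meth[i, bc]
    v[!is.na(v)]
  }
  v1 <- pick(pair[1]); v2 <- pick(pair[2])
  mw <- mannWhitney(v1, v2)
  medians <- c(stats::median(v1), stats::median(v2))
  names(medians) <- pair
  direction <- switch(mw$direction, group1_higher = "first_higher",
                      group2_higher = "second_higher", "none")
  list(gene = rownames(meth)[i], pair = pair, medians = medians,
       statistic = mw$statistic, p_value = mw$p_value,
       direction = direction, significant = mw$p_value < alpha)
}

#' Stage-wise methylation comparisons against normal
#'
#' Runs [compareMethylation()] for the pairs (N, S1)..(N, S4) and the
#' consecutive stage pairs, for one gene.
#'
#' @inheritParams compareMethylation
#' @return data.frame: pair, median_a, median_b, statistic, p_value,
#'   direction, significant.
#' @export
methylationProfile <- function(cohort, gene, alpha = 0.05) {
  pairs <- c(lapply(TUMOUR_STAGES, function(s) c("N", s)),
             list(c("S1", "S2"), c("S2", "S3"), c("S3", "S4")))
  rows <- lapply(pairs, function(p) {
    cmp <- tryCatch(compareMethylation(cohort, gene, p, alpha = alpha),
                    error = function(e) NULL)
    if (is.null(cmp)) return(NULL)
    data.frame(pair = paste(p, collapse = "/"),
               median_a = unname(cmp$medians[1]), median_b = unname(cmp$medians[2]),
               statistic = cmp$statistic, p_value = cmp$p_value,
               direction = cmp$direction, significant = cmp$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
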