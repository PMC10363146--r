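#' Jaccard index of two gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`, with J = 0 when both sets are
#' empty. Inputs are treated as sets (duplicates ignored).
#'
#' @param a,b character vectors of gene keys.
#' @return Jaccard index in \[0, 1\].
#' @examples
#' jaccardIndex(c("x", "y", "z"), c("y", "z", "w"))  # 0.5
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Transition between two phase gene sets
#'
#' For an ordered phase pair A -> B: lost = A \\ B, conserved =
#' A intersect B, acquired = B \\ A. Loss percentage is relative to the
#' source set A, gain percentage relative to the destination set B and
#' conservation relative to the union; all reported at 2 decimals
#' (round-half-to-even). Percentages over an empty reference set are 0.
#'
#' @param a,b character vectors of gene keys (source and destination sets).
#' @param from_group,to_group phase labels.
#' @return a [TransitionSummary-class].
#' @export
transition <- function(a, b, from_group = "A", to_group = "B") {
  a <- unique(a); b <- unique(b)
  lost <- setdiff(a, b)
  conserved <- intersect(a, b)
  acquired <- setdiff(b, a)
  nu <- length(union(a, b))
  pct <- function(num, den) if (den == 0) 0 else round(100 * num / den, 2)
  new("TransitionSummary",
      from_group = from_group, to_group = to_group,
      lost = lost, conserved = conserved, acquired = acquired,
      jaccard = jaccardIndex(a, b),
      pct_lost = pct(length(lost), length(a)),
      pct_acquired = pct(length(acquired), length(b)),
      pct_conserved_of_union = pct(length(conserved), nu))
}

setMethod("show", "TransitionSummary", function(object) {
  cat("Transition ", object@from_group, " -> ", object@to_group,
      ": lost ", length(object@lost), " (", object@pct_lost,
      "%), conserved ", length(object@conserved),
      ", acquired ", length(object@acquired), " (", object@pct_acquired,
      "%), Jaccard ", signif(object@jaccard, 4), "\n", sep = "")
})

#' Phase series of transitions across a stage profile
#'
#' Walks the fixed phase order (N, S1), (S1, S2), (S2, S3), (S3, S4) over
#' the thresholded gene sets of a stage profile; pairs with a missing side
#' are skipped with a warning.
#'
#' @param profile named list of [CoexpressionTable-class] (or plain
#'   character gene sets), names over N, S1..S4.
#' @return named list of [TransitionSummary-class] ("N.S1", "S1.S2", ...).
#' @export
phaseSeries <- function(profile) {
  sets <- lapply(profile, function(x) if (is(x, "CoexpressionTable")) geneSet(x) else x)
  out <- list()
  for (i in seq_len(length(STAGE_GROUPS) - 1L)) {
    from <- STAGE_GROUPS[i]; to <- STAGE_GROUPS[i + 1L]
    if (is.null(sets[[from]]) || is.null(sets[[to]])) {
      warning("phase ", from, "/", to, " skipped: missing group")
      next
    }
    out[[paste(from, to, sep = ".")]] <- transition(sets[[from]], sets[[to]], from, to)
  }
  out
}

#' Cross-cohort Jaccard similarity matrix
#'
#' Pairwise Jaccard between every (cohort, group) coexpressed-gene set,
#' rendered as integer percentages (round-half-to-even). Row/column labels
#' are `"COHORT.GROUP"`. The matrix is symmetric with a 100% diagonal for
#' non-empty sets.
#'
#' @param profiles named list (by cohort) of stage profiles.
#' @param groups groups to include (default all present).
#' @return symmetric numeric matrix of Jaccard percentages.
#' @export
crossCohortMatrix <- function(profiles, groups = STAGE_GROUPS) {
  if (length(profiles) < 2) stop("need at least 2 cohorts")
  sets <- list()
  for (co in names(profiles)) {
    for (g in intersect(groups, names(profiles[[co]]))) {
      x <- profiles[[co]][[g]]
      sets[[paste(co, g, sep = ".")]] <- if (is(x, "CoexpressionTable")) geneSet(x) else x
    }
  }
  k <- length(sets)
  m <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      m[i, j] <- m[j, i] <- round(100 * jaccardIndex(sets[[i]], sets[[j]]))
    }
  }
  m
}

#' Tabulate a phase series as a data.frame
#'
#' One row per transition: phase, set sizes, lost/conserved/acquired
#' counts, percentages and the Jaccard percentage.
#'
#' @param series list of [TransitionSummary-class] from [phaseSeries()].
#' @return data.frame report.
#' @export
transitionReport <- function(series) {
  do.call(rbind, lapply(series, function(s) {
    data.frame(
      phase = paste(s@from_group, s@to_group, sep = "/"),
      n_from = length(s@lost) + length(s@conserved),
      n_to = length(s@conserved) + length(s@acquired),
      n_lost = length(s@lost), n_conserved = length(s@conserved),
      n_acquired = length(s@acquired),
      pct_lost = s@pct_lost, pct_acquired = s@pct_acquired,
      pct_conserved_of_union = s@pct_conserved_of_union,
      jaccard_pct = round(100 * s@jaccard),
      stringsAsFactors = FALSE
    )
  }))
}
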