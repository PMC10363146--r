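#' Construct a StageCohort
#'
#' @param expression numeric genes x samples matrix (RSEM-normalized),
#'   rownames "SYMBOL|ENTREZ", colnames sample barcodes.
#' @param annotations data.frame with one row per expression sample:
#'   `barcode`, `cohort`, `tissue` ("normal"/"tumour"), `stage`
#'   ("N","S1".."S4","unknown"), `time_days`, `event`, `surv_ok`.
#' @param methylation optional beta-value matrix (same dialect); default
#'   none.
#' @param cohort cohort label; defaults to the annotation value.
#' @param truth optional list with the generating configuration (synthetic
#'   cohorts only).
#' @return a [StageCohort-class] object.
#' @export
StageCohort <- function(expression, annotations, methylation = NULL,
                        cohort = NULL, truth = list()) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  ids <- parseGeneId(rownames(expression))
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  stopifnot(all(colnames(expression) %in% ann$barcode))
  ann <- ann[match(colnames(expression), ann$barcode), , drop = FALSE]
  if (is.null(cohort)) cohort <- ann$cohort[1]
  if (is.null(ann$surv_ok)) ann$surv_ok <- !is.na(ann$time_days)
  cd <- DataFrame(barcode = ann$barcode, cohort = ann$cohort,
                  tissue = ann$tissue, stage = ann$stage,
                  time_days = ann$time_days, event = ann$event,
                  surv_ok = ann$surv_ok, row.names = ann$barcode)
  if (is.null(methylation)) {
    methylation <- matrix(numeric(0), nrow = 0, ncol = 0)
  }
  se <- SummarizedExperiment(
    assays = list(rsem = expression),
    rowData = DataFrame(symbol = ids$symbol, entrez = ids$entrez,
                        key = geneKey(ids$symbol, ids$entrez)),
    colData = cd
  )
  obj <- new("StageCohort", se, methylation = methylation, truth = truth)
  metadata(obj)$cohort <- cohort
  validObject(obj)
  obj
}

#' @rdname StageCohort-class
#' @export
setMethod("expressionMatrix", "StageCohort", function(x) assay(x, "rsem"))

#' @rdname StageCohort-class
#' @export
setMethod("methylationMatrix", "StageCohort", function(x) x@methylation)

#' @rdname StageCohort-class
#' @export
setMethod("sampleInfo", "StageCohort",
          function(x) as.data.frame(colData(x), stringsAsFactors = FALSE))

#' @rdname StageCohort-class
#' @export
setMethod("cohortName", "StageCohort", function(x) metadata(x)$cohort)

#' @rdname StageCohort-class
#' @export
setMethod("truthConfig", "StageCohort", function(x) x@truth)

#' @rdname StageCohort-class
#' @export
setMethod("groupSamples", "StageCohort", function(x, group) {
  stopifnot(group %in% c(STAGE_GROUPS, "unknown"))
  colnames(x)[colData(x)$stage == group]
})

setMethod("show", "StageCohort", function(object) {
  cd <- colData(object)
  counts <- table(factor(cd$stage, levels = c(STAGE_GROUPS, "unknown")))
  cat("StageCohort '", cohortName(object), "': ",
      nrow(object), " genes x ", ncol(object), " samples\n", sep = "")
  cat("  groups:", paste(sprintf("%s=%d", names(counts), counts), collapse = " "), "\n")
  cat("  methylation: ", nrow(object@methylation), " genes; ",
      if (length(object@truth)) "synthetic (truth embedded)" else "from files",
      "\n", sep = "")
})

#' Locate a gene row in a cohort
#'
#' Matches by full "SYMBOL|ENTREZ" id, by bare symbol, by Entrez id, or by
#' gene key.
#'
#' @param cohort a StageCohort.
#' @param gene character identifier.
#' @return integer row index.
#' @keywords internal
geneRow <- function(cohort, gene) {
  rd <- rowData(cohort)
  i <- which(rownames(cohort) == gene)
  if (!length(i)) i <- which(rd$key == gene)
  if (!length(i)) i <- which(rd$symbol == gene)
  if (!length(i)) i <- which(rd$entrez == suppressWarnings(as.integer(gene)))
  if (!length(i)) stop("gene not found in cohort: ", gene)
  i[1]
}
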