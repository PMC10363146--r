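#' @rdname StageCohort-class
#' @param x,object a `StageCohort` (or other class as documented).
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))

#' @rdname StageCohort-class
#' @export
setGeneric("methylationMatrix", function(x) standardGeneric("methylationMatrix"))

#' @rdname StageCohort-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname StageCohort-class
#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))

#' @rdname StageCohort-class
#' @export
setGeneric("truthConfig", function(x) standardGeneric("truthConfig"))

#' @rdname StageCohort-class
#' @param group a group label ("N", "S1".."S4").
#' @export
setGeneric("groupSamples", function(x, group) standardGeneric("groupSamples"))

#' Thresholded gene set of a coexpression table
#'
#' @param x a `CoexpressionTable`.
#' @return character vector of gene keys (Entrez id when known, symbol
#'   otherwise) of the genes passing the coexpression thresholds.
#' @export
setGeneric("geneSet", function(x) standardGeneric("geneSet"))

#' @rdname CoexpressionTable-class
#' @param x a `CoexpressionTable`.
#' @export
setGeneric("coexResults", function(x) standardGeneric("coexResults"))
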