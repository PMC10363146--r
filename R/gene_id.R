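#' Parse "SYMBOL|ENTREZ" gene identifiers
#'
#' Firehose row keys combine a HGNC symbol and a numeric Entrez id, e.g.
#' `"MYC|4609"`. An unknown symbol is written `"?"` (parsed to the empty
#' string); a missing Entrez id parses to 0. An id with neither part is
#' rejected.
#'
#' @param x character vector of identifiers.
#' @return data.frame with columns `symbol` (character) and `entrez`
#'   (non-negative integer, 0 = unknown).
#' @examples
#' parseGeneId(c("MYC|4609", "?|100130426", "TP53"))
#' @export
parseGeneId <- function(x) {
  stopifnot(is.character(x))
  parts <- strsplit(x, "|", fixed = TRUE)
  symbol <- vapply(parts, function(p) p[[1]], character(1))
  entrez <- vapply(parts, function(p) {
    if (length(p) < 2L) return(0L)
    v <- suppressWarnings(as.integer(p[[2]]))
    if (is.na(v) || v < 0L) 0L else v
  }, integer(1))
  symbol[symbol == "?"] <- ""
  bad <- symbol == "" & entrez == 0L
  if (any(bad)) {
    stop("unparseable gene identifier(s): ",
         paste(utils::head(x[bad], 5), collapse = ", "))
  }
  data.frame(symbol = symbol, entrez = entrez, stringsAsFactors = FALSE)
}

#' Render a gene identifier as "SYMBOL|ENTREZ"
#'
#' Inverse of [parseGeneId()]: an empty symbol renders as `"?"`, so rendering
#' round-trips through parsing.
#'
#' @param symbol character vector of symbols ("" = unknown).
#' @param entrez integer vector of Entrez ids (0 = unknown).
#' @export
formatGeneId <- function(symbol, entrez) {
  s <- ifelse(symbol == "", "?", symbol)
  paste0(s, "|", entrez)
}

#' Comparable gene key: Entrez id with symbol fallback
#'
#' Gene sets are compared on Entrez ids (symbols are aliased and unstable);
#' when the Entrez id is unknown the symbol stands in.
#'
#' @inheritParams formatGeneId
#' @return character vector of keys.
#' @export
geneKey <- function(symbol, entrez) {
  ifelse(entrez > 0L, as.character(entrez), symbol)
}
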