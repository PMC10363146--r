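## Readers/writers for the Broad Firehose Level-3 tabular dialect:
## expression and methylation matrices keyed by "SYMBOL|ENTREZ" with an
## optional second header row repeating a per-column datatype tag
## ("normalized_count", "Beta_value", ...), and Clinical_Pick_Tier1 tables
## keyed by patient.

#' Read a Firehose-style expression matrix
#'
#' Expects a TSV whose first column holds `"SYMBOL|ENTREZ"` row keys and
#' whose first header row carries sample barcodes. A Firehose datatype-tag
#' row (every data cell the same non-numeric token, e.g.
#' `"normalized_count"`) directly under the header is stripped. `"NA"`
#' cells become missing values and are resolved by `missing_policy`:
#' `"drop_gene"` removes any gene with a missing value, `"impute_zero"`
#' replaces them with 0. Duplicate (symbol, entrez) rows keep the row with
#' the larger total expression (ties: first in file order).
#'
#' @param path TSV file path.
#' @param missing_policy `"drop_gene"` (default) or `"impute_zero"`.
#' @return numeric matrix, rownames `"SYMBOL|ENTREZ"`, colnames barcodes.
#' @export
readExpression <- function(path, missing_policy = c("drop_gene", "impute_zero")) {
  missing_policy <- match.arg(missing_policy)
  lines <- readLines(path)
  if (length(lines) < 2) stop("format error at line 1: no data rows in ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("format error at line 1: header needs a key column and >= 1 sample")
  barcodes <- header[-1]
  if (anyDuplicated(barcodes))
    stop("validation error: duplicate sample barcode(s): ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    stop("format error at line ", which(widths != length(header))[1] + 1L,
         ": expected ", length(header), " fields")
  }
  ## Firehose dialect: second header row repeats a datatype tag per column
  first <- body[[1]][-1]
  if (length(body) > 1 && all(is.na(suppressWarnings(as.numeric(first)))) &&
      length(unique(first)) == 1L) {
    body <- body[-1]
  }
  keys <- vapply(body, `[[`, character(1), 1L)
  vals <- vapply(body, function(p) {
    v <- p[-1]
    v[v %in% c("NA", "na", "NaN", "")] <- NA
    suppressWarnings(as.numeric(v))
  }, numeric(length(barcodes)))
  mat <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(barcodes))
  dimnames(mat) <- list(keys, barcodes)
  ids <- parseGeneId(keys)
  rownames(mat) <- formatGeneId(ids$symbol, ids$entrez)
  ## de-duplication policy: keep the duplicate with the larger total signal
  dupkey <- paste(ids$symbol, ids$entrez, sep = "\r")
  if (anyDuplicated(dupkey)) {
    tot <- rowSums(mat, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_len(nrow(mat)), dupkey), function(i) i[which.max(tot[i])]),
                   use.names = FALSE)
    mat <- mat[sort(keep), , drop = FALSE]
  }
  if (missing_policy == "drop_gene") {
    mat <- mat[!apply(is.na(mat), 1, any), , drop = FALSE]
  } else {
    mat[is.na(mat)] <- 0
  }
  if (any(mat < 0)) stop("validation error: negative expression values")
  mat
}

#' Read a Firehose methylation-preprocess matrix
#'
#' Same dialect as [readExpression()] but values are beta-values, validated
#' to lie in \[0, 1\]. The Meth.by_min_expr_corr preprocessing upstream maps
#' each gene to one probe, so the file is one beta row per gene.
#'
#' @inheritParams readExpression
#' @return numeric matrix of beta-values.
#' @export
readMethylation <- function(path, missing_policy = c("drop_gene", "impute_zero")) {
  mat <- readExpression(path, missing_policy = match.arg(missing_policy))
  if (any(mat < 0, na.rm = TRUE) || any(mat > 1, na.rm = TRUE))
    stop("validation error: beta-values outside [0, 1]")
  mat
}

#' Classify a TCGA-style barcode into tissue class
#'
#' TCGA encodes the sample type in characters 14-15 of the barcode (the
#' first two characters of the fourth dash-separated field): codes 01-09
#' are tumour, 10-19 normal, 20-29 control (rejected). Synthetic barcodes
#' follow the same field layout.
#'
#' @param barcode character vector of barcodes.
#' @return character vector, `"tumour"` or `"normal"`.
#' @examples
#' classifyBarcode("TCGA-B0-4690-01A-01R-1305-07")  # tumour
#' classifyBarcode("TCGA-B0-4690-11A-01R-1305-07")  # normal
#' @export
classifyBarcode <- function(barcode) {
  vapply(barcode, function(b) {
    parts <- strsplit(b, "-", fixed = TRUE)[[1]]
    if (length(parts) < 4)
      stop("classification error: barcode lacks a sample-type field: ", b)
    code <- suppressWarnings(as.integer(substr(parts[4], 1, 2)))
    if (is.na(code)) stop("classification error: unparseable sample-type code: ", b)
    if (code >= 1 && code <= 9) return("tumour")
    if (code >= 10 && code <= 19) return("normal")
    stop("classification error: control/out-of-range sample-type code ", code, ": ", b)
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize a pathologic-stage string
#'
#' Case-insensitive; sub-stages (IA/IB, ...) collapse to the parent stage
#' since the analysis works at stage resolution I-IV. Anything else
#' (including bracketed discrepancy markers) maps to `"unknown"`.
#'
#' @param x character vector of stage strings.
#' @return character vector over `"S1".."S4"`, `"unknown"`.
#' @export
normalizeStage <- function(x) {
  s <- tolower(trimws(x))
  out <- rep("unknown", length(s))
  m <- regmatches(s, regexec("^stage[[:space:]]+(iv|iii|ii|i)[abc]?$", s))
  rom <- vapply(m, function(p) if (length(p)) p[2] else NA_character_, character(1))
  map <- c(i = "S1", ii = "S2", iii = "S3", iv = "S4")
  hit <- !is.na(rom)
  out[hit] <- map[rom[hit]]
  ## already-normalized labels pass through (idempotence)
  out[s %in% c("s1", "s2", "s3", "s4")] <- toupper(s[s %in% c("s1", "s2", "s3", "s4")])
  out[s == "n"] <- "N"
  out
}

#' Read a Firehose Clinical_Pick_Tier1-style table
#'
#' Expects a TSV keyed by patient barcode with columns (dialects accepted
#' case-insensitively, spaces for underscores): `pathologic_stage`,
#' `vital_status`, `days_to_death`, `days_to_last_followup`. Follow-up time
#' is `days_to_death` for deceased patients, else
#' `days_to_last_followup`; a patient with neither time is retained but
#' flagged unusable for survival.
#'
#' @param path TSV file path.
#' @param cohort cohort label attached to every row.
#' @return data.frame with columns `patient`, `stage`, `time_days`,
#'   `event`, `surv_ok`, `cohort`.
#' @export
readClinical <- function(path, cohort = "SYNTH") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- tolower(gsub("[. ]", "_", colnames(df)))
  pick <- function(name) {
    i <- which(cn == name)
    if (!length(i)) stop("format error: clinical table lacks column '", name, "'")
    df[[i[1]]]
  }
  patient <- toupper(as.character(df[[1]]))
  stage <- normalizeStage(as.character(pick("pathologic_stage")))
  vital <- tolower(trimws(as.character(pick("vital_status"))))
  event <- vital %in% c("dead", "deceased", "1", "true")
  num <- function(v) suppressWarnings(as.numeric(as.character(v)))
  death <- num(pick("days_to_death"))
  follow <- num(pick("days_to_last_followup"))
  time_days <- ifelse(event, death, follow)
  ## deceased patients missing days_to_death fall back to follow-up
  time_days[event & is.na(time_days)] <- follow[event & is.na(time_days)]
  surv_ok <- !is.na(time_days) & time_days >= 0
  data.frame(patient = patient, stage = stage, time_days = time_days,
             event = event, surv_ok = surv_ok, cohort = cohort,
             stringsAsFactors = FALSE)
}

#' Assemble a StageCohort from Firehose-style files
#'
#' Joins expression samples to clinical rows by the 12-character patient
#' prefix of the barcode; tissue class comes from the barcode sample-type
#' code; normal samples get stage `"N"`, tumour samples the patient's
#' pathologic stage (or `"unknown"`). All samples of a patient inherit the
#' patient's stage and survival record; multiple tumour samples per patient
#' are kept.
#'
#' @param expression_path,clinical_path,methylation_path file paths
#'   (methylation optional).
#' @param cohort cohort label.
#' @param missing_policy forwarded to [readExpression()].
#' @return a [StageCohort-class].
#' @export
readCohort <- function(expression_path, clinical_path, methylation_path = NULL,
                       cohort = "SYNTH", missing_policy = "drop_gene") {
  expr <- readExpression(expression_path, missing_policy)
  clin <- readClinical(clinical_path, cohort = cohort)
  meth <- if (!is.null(methylation_path)) readMethylation(methylation_path, missing_policy)
  ann <- annotateSamples(colnames(expr), clin, cohort)
  StageCohort(expr, ann, methylation = meth, cohort = cohort)
}

#' Annotate sample barcodes with tissue, stage and survival
#'
#' @param barcodes sample barcodes.
#' @param clinical data.frame from [readClinical()].
#' @param cohort cohort label.
#' @return annotation data.frame accepted by [StageCohort()].
#' @export
annotateSamples <- function(barcodes, clinical, cohort = "SYNTH") {
  tissue <- classifyBarcode(barcodes)
  patient <- toupper(substr(barcodes, 1, 12))
  i <- match(patient, clinical$patient)
  stage <- ifelse(tissue == "normal", "N",
                  ifelse(is.na(i), "unknown", clinical$stage[i]))
  stage[tissue == "tumour" & stage == "N"] <- "unknown"
  data.frame(
    barcode = barcodes, cohort = cohort, tissue = tissue, stage = stage,
    time_days = ifelse(is.na(i), NA_real_, clinical$time_days[i]),
    event = ifelse(is.na(i), FALSE, clinical$event[i]),
    surv_ok = ifelse(is.na(i), FALSE, clinical$surv_ok[i]),
    stringsAsFactors = FALSE
  )
}

#' Write a matrix in the Firehose dialect
#'
#' Emits the two-row header (barcodes, then a repeated datatype tag) so the
#' output re-reads through [readExpression()] / [readMethylation()]
#' unchanged. Values are printed at full double precision.
#'
#' @param mat numeric matrix with gene-id rownames and barcode colnames.
#' @param path output path.
#' @param tag datatype tag for the second header row.
#' @export
writeExpression <- function(mat, path, tag = "normalized_count") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Hybridization REF", colnames(mat)), collapse = "\t"), con)
  writeLines(paste(c("gene", rep(tag, ncol(mat))), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format(mat[i, ], digits = 17, trim = TRUE,
                                     scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
}

#' Write sample annotations as TSV
#'
#' Fixed column order: barcode, cohort, tissue, stage, time_days, event.
#'
#' @param ann annotation data.frame (e.g. from [sampleInfo()]).
#' @param path output path.
#' @export
writeAnnotations <- function(ann, path) {
  utils::write.table(ann[, c("barcode", "cohort", "tissue", "stage", "time_days", "event")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
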