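## Fixture builders shared across test files. All fixtures are generated
## in code at test time; nothing is read from disk except what the tests
## themselves write to tempdir().

# tiny Firehose-dialect expression TSV; returns its path
writeFirehoseFixture <- function(values = NULL, tag = "normalized_count",
                                 barcodes = c("TCGA-AA-0001-01A", "TCGA-AA-0002-11A")) {
  if (is.null(values)) {
    values <- matrix(c(10, 20, 0, 5, 3.5, 7), nrow = 3, byrow = TRUE,
                     dimnames = list(c("MYC|4609", "TP53|7157", "?|100130426"),
                                     barcodes))
  }
  path <- tempfile(fileext = ".tsv")
  lines <- paste(c("Hybridization REF", colnames(values)), collapse = "\t")
  if (!is.null(tag)) {
    lines <- c(lines, paste(c("gene", rep(tag, ncol(values))), collapse = "\t"))
  }
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], format(values[i, ], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  path
}

# clinical TSV in the patient-keyed dialect; rows = list of character vectors
writeClinicalFixture <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- "patient_barcode\tpathologic_stage\tvital_status\tdays_to_death\tdays_to_last_followup"
  writeLines(c(header, vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

# small, fast synthetic configuration used where full size is unnecessary
smallSynthConfig <- function(seed = 1, n_genes = 300, ...) {
  synthConfig(
    n_genes = n_genes,
    samples_per_group = c(N = 30, S1 = 30, S2 = 30, S3 = 30, S4 = 30),
    planted_sets = list(N = 1:60, S1 = c(1:10, 61:90), S2 = c(1:10, 76:120),
                        S3 = c(1:10, 101:140), S4 = c(1:10, 121:160)),
    de_genes = 1:10,
    seed = seed, ...
  )
}

# brute-force Jaccard via logical membership vectors (independent of
# set-operation code paths)
bitsetJaccard <- function(a, b, universe) {
  va <- universe %in% a
  vb <- universe %in% b
  u <- sum(va | vb)
  if (u == 0) 0 else sum(va & vb) / u
}

# exact two-sided permutation p-value for Spearman, enumerating all n!
# orderings of y
spearmanPermP <- function(x, y) {
  permn <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in permn(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rho_obs <- stats::cor(rank(x), rank(y))
  rhos <- vapply(permn(seq_along(y)), function(p) stats::cor(rank(x), rank(y[p])),
                 numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# exact two-sided Mann-Whitney p by enumerating group-label assignments
mwEnumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  ustat <- function(i) {
    xs <- pooled[i]; ys <- pooled[-i]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- ustat(seq_len(n1))
  mu <- n1 * (length(pooled) - n1) / 2
  us <- apply(idx, 2, ustat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# product-limit survival computed directly from the definition
handKM <- function(times, events) {
  ut <- sort(unique(times[events]))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    n_i <- sum(times >= ut[k])
    d_i <- sum(times == ut[k] & events)
    s <- s * (1 - d_i / n_i)
    out[k] <- s
  }
  list(times = ut, surv = out)
}
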