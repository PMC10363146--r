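## Seeded generator for stage-labelled cohorts with known structure:
## planted hub-correlated modules per group, tumour expression shifts,
## group-specific promoter methylation and quartile-linked survival
## hazards. Every downstream stage of the pipeline is testable against the
## embedded ground truth without external data.

#' Default planted per-group module layout
#'
#' Two variants sharing a 4-gene cross-cohort core (genes 1-4) inside a
#' 15/15-gene all-stage core, with per-stage extras that overlap between
#' consecutive stages. Variant "A": all-stage core 1-15; variant "B":
#' all-stage core \{1-4, 16-26\}. Extras are identical across variants and
#' never survive the four-stage intersection, so the consistent sets are
#' exactly the cores and their cross-cohort intersection is genes 1-4.
#'
#' @param variant `"A"` or `"B"`.
#' @return named list of integer gene-index vectors for N, S1..S4.
#' @export
defaultPlantedSets <- function(variant = c("A", "B")) {
  variant <- match.arg(variant)
  core <- if (variant == "A") 1:15 else c(1:4, 16:26)
  list(
    N = 1:200,
    S1 = c(core, 201:285),
    S2 = c(core, 246:380),
    S3 = c(core, 331:435),
    S4 = c(core, 401:495)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the reference simulation: 2000 genes plus the hub,
#' 100 samples per group, latent-factor loading 0.95, tumour log-shift 1.0
#' on the core genes, hypomethylated tumour stages, hazard ratio 3 for the
#' top expression quartile of the designated prognostic gene and 20%
#' independent censoring.
#'
#' @param n_genes number of non-hub genes.
#' @param samples_per_group named integer vector over N, S1..S4 (each
#'   >= 4).
#' @param hub_symbol,hub_entrez identity of the hub gene.
#' @param planted_sets named list of gene-index vectors per group (indices
#'   in 1..n_genes).
#' @param coexpr_strength latent-factor loading a in \[0, 1): a planted
#'   gene's latent value is `a * hub_signal + (1 - a) * noise`, then
#'   monotonically mapped to a non-negative expression scale (Spearman
#'   correlation survives the transform).
#' @param de_genes gene indices receiving `de_shift` on the log scale in
#'   tumour groups (the hub is always shifted).
#' @param de_shift tumour log-expression shift.
#' @param meth_means named per-group mean beta-value in (0, 1) for the hub
#'   gene's promoter; other genes centre at 0.5.
#' @param meth_sd beta-value standard deviation.
#' @param prognostic_gene index of the gene whose top expression quartile
#'   carries the elevated hazard.
#' @param hazard_ratio_high hazard multiplier for the top quartile (> 0).
#' @param censor_rate target fraction of censored tumour samples, in
#'   \[0, 1).
#' @param base_hazard baseline exponential hazard per day.
#' @param cohort cohort label.
#' @param seed integer seed; expanded into independent substreams for
#'   expression, methylation and survival so that, e.g., adding genes does
#'   not perturb the survival draws.
#' @return validated config list of class `"synth_config"`.
#' @export
synthConfig <- function(n_genes = 2000,
                        samples_per_group = c(N = 100, S1 = 100, S2 = 100,
                                              S3 = 100, S4 = 100),
                        hub_symbol = "MYC", hub_entrez = 4609L,
                        planted_sets = defaultPlantedSets("A"),
                        coexpr_strength = 0.95,
                        de_genes = 1:26, de_shift = 1.0,
                        meth_means = c(N = 0.60, S1 = 0.30, S2 = 0.35,
                                       S3 = 0.35, S4 = 0.40),
                        meth_sd = 0.05,
                        prognostic_gene = 1L,
                        hazard_ratio_high = 3,
                        censor_rate = 0.2,
                        base_hazard = log(2) / 1000,
                        cohort = "SYNTH",
                        seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              samples_per_group = samples_per_group,
              hub_symbol = hub_symbol, hub_entrez = as.integer(hub_entrez),
              planted_sets = lapply(planted_sets, as.integer),
              coexpr_strength = coexpr_strength,
              de_genes = as.integer(de_genes), de_shift = de_shift,
              meth_means = meth_means, meth_sd = meth_sd,
              prognostic_gene = as.integer(prognostic_gene),
              hazard_ratio_high = hazard_ratio_high,
              censor_rate = censor_rate, base_hazard = base_hazard,
              cohort = cohort, seed = as.integer(seed))
  validateSynthConfig(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validateSynthConfig <- function(cfg) {
  err <- function(...) stop("config error: ", ...)
  if (cfg$n_genes < 1) err("n_genes must be positive")
  if (!all(STAGE_GROUPS %in% names(cfg$samples_per_group)))
    err("samples_per_group must name all of ", paste(STAGE_GROUPS, collapse = ", "))
  if (any(cfg$samples_per_group < 4)) err("samples_per_group values must be >= 4")
  if (!all(names(cfg$planted_sets) %in% STAGE_GROUPS))
    err("planted_sets names must be groups")
  if (any(unlist(cfg$planted_sets) < 1) || any(unlist(cfg$planted_sets) > cfg$n_genes))
    err("planted sets must index genes in 1..n_genes")
  if (cfg$coexpr_strength < 0 || cfg$coexpr_strength >= 1)
    err("coexpr_strength must lie in [0, 1)")
  if (cfg$hazard_ratio_high <= 0) err("hazard_ratio_high must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    err("censor_rate must lie in [0, 1)")
  if (any(cfg$meth_means <= 0) || any(cfg$meth_means >= 1))
    err("meth_means must lie in (0, 1)")
  if (cfg$prognostic_gene < 1 || cfg$prognostic_gene > cfg$n_genes)
    err("prognostic_gene out of range")
  invisible(TRUE)
}

## gene ids: hub first, then G1..Gn with synthetic Entrez ids 100000 + i
synthGeneIds <- function(cfg) {
  c(formatGeneId(cfg$hub_symbol, cfg$hub_entrez),
    formatGeneId(paste0("G", seq_len(cfg$n_genes)), 100000L + seq_len(cfg$n_genes)))
}

#' Gene keys of a planted set
#'
#' @param config a `synth_config`.
#' @param group group label.
#' @return character vector of gene keys for the planted indices.
#' @export
plantedKeys <- function(config, group) {
  idx <- config$planted_sets[[group]]
  if (is.null(idx)) stop("group not configured: ", group)
  as.character(100000L + idx)
}

#' Ground-truth transition implied by the planted sets
#'
#' @param config a `synth_config`.
#' @param pair character vector of two configured groups.
#' @return a [TransitionSummary-class] computed from the planted sets.
#' @export
plantedTruth <- function(config, pair) {
  stopifnot(length(pair) == 2)
  transition(plantedKeys(config, pair[1]), plantedKeys(config, pair[2]),
             pair[1], pair[2])
}

#' Generate a synthetic stage cohort
#'
#' For each group, a standard-normal latent hub signal is drawn per
#' sample; each planted gene's latent value is
#' `a * hub + (1 - a) * noise` with `a = coexpr_strength`, non-planted
#' genes are independent noise, and all latent values map through
#' `exp(meanlog + value)` to a non-negative RSEM-like scale (a strictly
#' monotone transform, so planted Spearman correlations are preserved).
#' Core/`de_genes` (and the hub) gain `de_shift` on the log scale in
#' tumour groups. The hub promoter's beta-values are clamped normal draws
#' around the group's `meth_means`; other genes centre at 0.5. Tumour
#' survival is exponential with the hazard multiplied by
#' `hazard_ratio_high` for samples strictly above the 75th percentile of
#' the prognostic gene's tumour expression, with independent exponential
#' censoring calibrated to `censor_rate`.
#'
#' The seed expands into per-component substreams (expression,
#' methylation, survival), so the same seed is bit-reproducible and
#' enlarging one component leaves the others' draws unchanged.
#'
#' @param config a `synth_config` from [synthConfig()].
#' @return a [StageCohort-class] with the config embedded as truth.
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synthConfig, config)
  validateSynthConfig(config)
  cfg <- config
  set.seed(cfg$seed)
  ## substreams: one per expression group plus methylation and survival,
  ## so changing one component's size never shifts another's draws
  substream <- sample.int(.Machine$integer.max - 1L, 2 + length(STAGE_GROUPS))

  ng <- cfg$n_genes + 1L            # hub + genes
  groups <- STAGE_GROUPS
  nper <- cfg$samples_per_group[groups]
  total <- sum(nper)
  stage <- rep(groups, nper)
  tissue <- ifelse(stage == "N", "normal", "tumour")
  barcode <- sprintf("SYNT-%02d-%04d-%s",
                     rep(seq_along(groups), nper),
                     unlist(lapply(nper, seq_len)),
                     ifelse(tissue == "normal", "11A", "01A"))

  ## --- expression substreams (one per group) ---
  a <- cfg$coexpr_strength
  meanlog <- 4
  expr <- matrix(0, nrow = ng, ncol = total)
  col0 <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]; n <- nper[[gi]]
    cols <- col0 + seq_len(n); col0 <- col0 + n
    set.seed(substream[2 + gi])
    h <- stats::rnorm(n)
    shift <- if (g == "N") 0 else cfg$de_shift
    expr[1, cols] <- exp(meanlog + h + shift)
    planted <- cfg$planted_sets[[g]]
    ## row-major fill: gene i always consumes draws (i-1)*n+1 .. i*n, so
    ## enlarging n_genes leaves earlier genes' values untouched
    eps <- matrix(stats::rnorm(cfg$n_genes * n), nrow = cfg$n_genes, byrow = TRUE)
    z <- eps
    if (length(planted)) {
      z[planted, ] <- a * matrix(h, nrow = length(planted), ncol = n, byrow = TRUE) +
        (1 - a) * eps[planted, , drop = FALSE]
    }
    deshift <- numeric(cfg$n_genes)
    if (g != "N") deshift[cfg$de_genes] <- cfg$de_shift
    expr[-1, cols] <- exp(meanlog + z + deshift)
  }
  gene_ids <- synthGeneIds(cfg)
  dimnames(expr) <- list(gene_ids, barcode)

  ## --- methylation substream ---
  set.seed(substream[1])
  meth <- matrix(stats::rnorm(ng * total, mean = 0.5, sd = cfg$meth_sd),
                 nrow = ng, dimnames = list(gene_ids, barcode))
  for (g in groups) {
    cols <- which(stage == g)
    meth[1, cols] <- stats::rnorm(length(cols), mean = cfg$meth_means[[g]],
                                  sd = cfg$meth_sd)
  }
  meth[meth < 0] <- 0
  meth[meth > 1] <- 1

  ## --- survival substream ---
  set.seed(substream[2])
  time_days <- rep(NA_real_, total)
  event <- rep(FALSE, total)
  tum <- which(tissue == "tumour")
  pv <- expr[1L + cfg$prognostic_gene, tum]
  q75 <- stats::quantile(pv, 0.75, names = FALSE, type = 7)
  high <- pv > q75
  hazard <- cfg$base_hazard * ifelse(high, cfg$hazard_ratio_high, 1)
  tdeath <- stats::rexp(length(tum), rate = hazard)
  if (cfg$censor_rate > 0) {
    crate <- cfg$base_hazard * cfg$censor_rate / (1 - cfg$censor_rate)
    tcens <- stats::rexp(length(tum), rate = crate)
  } else {
    tcens <- rep(Inf, length(tum))
  }
  time_days[tum] <- pmin(tdeath, tcens)
  event[tum] <- tdeath <= tcens

  ann <- data.frame(barcode = barcode, cohort = cfg$cohort, tissue = tissue,
                    stage = stage, time_days = time_days, event = event,
                    surv_ok = !is.na(time_days), stringsAsFactors = FALSE)
  StageCohort(expr, ann, methylation = meth, cohort = cfg$cohort,
              truth = unclass(cfg))
}

#' Write a synthetic cohort as Firehose-dialect files
#'
#' Writes `expression.tsv`, `methylation.tsv`, `clinical.tsv` (readable by
#' [readCohort()]) and `truth.json` into a directory.
#'
#' @param cohort a [StageCohort-class] (typically from [simulateCohort()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
writeCohortFiles <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "methylation.tsv",
                            "clinical.tsv", "truth.json"))
  writeExpression(expressionMatrix(cohort), paths[1], tag = "normalized_count")
  writeExpression(methylationMatrix(cohort), paths[2], tag = "Beta_value")
  info <- sampleInfo(cohort)
  tum <- info[info$tissue == "tumour", ]
  stage_str <- c(S1 = "stage i", S2 = "stage ii", S3 = "stage iii",
                 S4 = "stage iv", unknown = "[discrepancy]")
  clin <- data.frame(
    patient_barcode = toupper(substr(tum$barcode, 1, 12)),
    pathologic_stage = stage_str[tum$stage],
    vital_status = ifelse(tum$event, "dead", "alive"),
    days_to_death = ifelse(tum$event, tum$time_days, NA),
    days_to_last_followup = ifelse(tum$event, NA, tum$time_days),
    stringsAsFactors = FALSE
  )
  clin <- clin[!duplicated(clin$patient_barcode), ]
  utils::write.table(format(clin, digits = 17, trim = TRUE), paths[3],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- truthConfig(cohort)
  if (length(truth)) {
    jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
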