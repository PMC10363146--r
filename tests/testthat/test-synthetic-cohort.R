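test_that("generation is bit-reproducible from the seed", {
  cfg <- smallSynthConfig(seed = 61)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(expressionMatrix(a), expressionMatrix(b))
  expect_identical(methylationMatrix(a), methylationMatrix(b))
  expect_identical(sampleInfo(a), sampleInfo(b))
  # a different seed changes the draws
  c <- simulateCohort(smallSynthConfig(seed = 62))
  expect_false(identical(expressionMatrix(a), expressionMatrix(c)))
})

test_that("substreams isolate components: more genes, same survival", {
  base <- smallSynthConfig(seed = 63)
  bigger <- smallSynthConfig(seed = 63, n_genes = 400)
  s1 <- sampleInfo(simulateCohort(base))
  s2 <- sampleInfo(simulateCohort(bigger))
  # prognostic gene (index 1) draws first in the expression stream, so the
  # quartile assignment and the survival substream are unchanged
  expect_identical(s1$time_days, s2$time_days)
  expect_identical(s1$event, s2$event)
})

test_that("generated matrices satisfy the domain invariants", {
  cfg <- smallSynthConfig(seed = 64)
  co <- simulateCohort(cfg)
  expect_true(all(expressionMatrix(co) >= 0))
  beta <- methylationMatrix(co)
  expect_true(all(beta >= 0 & beta <= 1))
  info <- sampleInfo(co)
  expect_equal(as.vector(table(info$stage)[c("N", "S1", "S2", "S3", "S4")]),
               rep(30L, 5))
  expect_true(all(is.na(info$time_days[info$tissue == "normal"])))
  expect_true(all(info$time_days[info$tissue == "tumour"] >= 0))
  expect_s4_class(co, "StageCohort")
  expect_true(validObject(co))
})

test_that("planted correlation strength controls hub correlation", {
  cfg <- synthConfig(n_genes = 200,
                     samples_per_group = c(N = 30, S1 = 50, S2 = 30, S3 = 30, S4 = 30),
                     planted_sets = list(S1 = 1:50), coexpr_strength = 0.95,
                     de_genes = integer(0), seed = 7)
  co <- simulateCohort(cfg)
  s1 <- groupSamples(co, "S1")
  mat <- expressionMatrix(co)[, s1]
  rs <- vapply(1:50, function(i)
    spearmanTest(mat["MYC|4609", ], mat[i + 1, ])$rs, numeric(1))
  expect_gt(median(rs), 0.6)

  # zero strength: planted genes are null; selection rate at chance level
  null_cfg <- synthConfig(n_genes = 500,
                          samples_per_group = c(N = 100, S1 = 100, S2 = 100,
                                                S3 = 100, S4 = 100),
                          planted_sets = list(S1 = 1:100), coexpr_strength = 0,
                          de_genes = integer(0), seed = 8)
  nco <- simulateCohort(null_cfg)
  tb <- coexpressedSet(nco, "S1", "MYC|4609")
  res <- coexResults(tb)
  planted_rows <- res$gene %in% plantedKeys(null_cfg, "S1")
  expect_lt(abs(median(res$rs[planted_rows])), 0.15)
  expect_lte(mean(abs(res$rs) > 0.3 & res$p < 0.05), 0.01)
})

test_that("planted truth reproduces set arithmetic on the configuration", {
  cfg <- synthConfig(n_genes = 200,
                     samples_per_group = c(N = 10, S1 = 10, S2 = 10, S3 = 10, S4 = 10),
                     planted_sets = list(S1 = 1:60, S2 = 41:120), seed = 65)
  tr <- plantedTruth(cfg, c("S1", "S2"))
  expect_length(tr@conserved, 20)
  expect_equal(tr@jaccard, 20 / 120, tolerance = 1e-12)
  same <- synthConfig(n_genes = 50,
                      samples_per_group = c(N = 10, S1 = 10, S2 = 10, S3 = 10, S4 = 10),
                      planted_sets = list(S1 = 1:20, S2 = 1:20, S3 = 21:40),
                      prognostic_gene = 1, seed = 66)
  expect_equal(plantedTruth(same, c("S1", "S2"))@jaccard, 1)
  expect_length(plantedTruth(same, c("S1", "S2"))@lost, 0)
  expect_equal(plantedTruth(same, c("S2", "S3"))@jaccard, 0)
  expect_error(plantedTruth(same, c("S1", "S4")), "not configured")
})

test_that("config invariants are enforced", {
  expect_error(synthConfig(samples_per_group = c(N = 3, S1 = 10, S2 = 10,
                                                 S3 = 10, S4 = 10)), ">= 4")
  expect_error(synthConfig(n_genes = 10, planted_sets = list(S1 = 1:20)),
               "1..n_genes")
  expect_error(synthConfig(hazard_ratio_high = 0), "hazard_ratio_high")
  expect_error(synthConfig(coexpr_strength = 1), "coexpr_strength")
  expect_error(synthConfig(censor_rate = 1), "censor_rate")
})

test_that("written cohort files round-trip through the Firehose readers", {
  cfg <- synthConfig(n_genes = 40,
                     samples_per_group = c(N = 10, S1 = 10, S2 = 10, S3 = 10, S4 = 10),
                     planted_sets = list(S1 = 1:10, S2 = 1:10, S3 = 1:10, S4 = 1:10),
                     de_genes = 1:5, seed = 67)
  co <- simulateCohort(cfg)
  dir <- file.path(tempdir(), "synthcohort")
  paths <- writeCohortFiles(co, dir)
  back <- readCohort(paths[1], paths[3], paths[2], cohort = "SYNTH")
  expect_identical(expressionMatrix(back), expressionMatrix(co))
  expect_identical(methylationMatrix(back), methylationMatrix(co))
  i1 <- sampleInfo(co); i2 <- sampleInfo(back)
  expect_equal(i2$stage, i1$stage)
  expect_equal(i2$tissue, i1$tissue)
  expect_equal(i2$event, i1$event)
  expect_equal(i2$time_days, i1$time_days, tolerance = 1e-9)
})
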