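test_that("consistent genes are the order-invariant stage intersection", {
  sets <- list(N = c("n1", "c", "x"), S1 = c("c", "x", "a"), S2 = c("c", "x", "b"),
               S3 = c("c", "x"), S4 = c("c", "y"))
  cons <- consistentGenes(sets)
  expect_setequal(cons, "c")          # normal group plays no part
  expect_false("n1" %in% cons)
  # order of intersection is immaterial
  expect_setequal(consistentGenes(sets[c("S4", "S2", "S1", "S3")]), cons)
  # one empty stage empties the intersection
  sets$S3 <- character(0)
  expect_length(consistentGenes(sets), 0)
  # identical stages return that set
  same <- list(S1 = c("a", "b"), S2 = c("a", "b"), S3 = c("a", "b"), S4 = c("a", "b"))
  expect_setequal(consistentGenes(same), c("a", "b"))
  expect_error(consistentGenes(sets[c("S1", "S2")]), "S3")
})

test_that("cross-cohort consistency intersects per-cohort sets", {
  expect_setequal(crossCohortConsistent(list(A = c("1", "2", "3"), B = c("2", "3", "4"))),
                  c("2", "3"))
  expect_length(crossCohortConsistent(list(A = c("1"), B = c("2"))), 0)
  expect_equal(crossCohortConsistent(list(A = c("1", "7"), B = c("7"), C = c("7", "9"))),
               "7")
  expect_error(crossCohortConsistent(list(A = c("1"))), "2 cohorts")
})

test_that("quartile split uses strict interpolated boundaries", {
  v <- stats::setNames(as.numeric(1:100), paste0("s", 1:100))
  qs <- quartileSplit(v)
  expect_length(qs$high, 25)
  expect_length(qs$low, 25)
  expect_length(intersect(qs$high, qs$low), 0)
  expect_true(all(v[qs$high] > qs$q75))
  expect_true(all(v[qs$low] < qs$q25))

  # linear interpolation on 1..8: q25 = 2.75, q75 = 6.25
  v8 <- stats::setNames(as.numeric(1:8), paste0("s", 1:8))
  qs8 <- quartileSplit(v8)
  expect_equal(qs8$q25, 2.75)
  expect_equal(qs8$q75, 6.25)
  expect_setequal(qs8$low, c("s1", "s2"))
  expect_setequal(qs8$high, c("s7", "s8"))

  # boundary ties enter neither arm
  vt <- stats::setNames(c(1, 2, 3, 3, 3, 3, 3, 3, 4, 5, 6, 7), paste0("t", 1:12))
  qt <- quartileSplit(vt)
  expect_false(any(vt[qt$high] == qt$q75))
  expect_false(any(vt[qt$low] == qt$q25))

  # degenerate: all equal leaves both arms empty and unscreenable
  ve <- stats::setNames(rep(5, 10), paste0("e", 1:10))
  qe <- quartileSplit(ve)
  expect_length(qe$high, 0)
  expect_length(qe$low, 0)
  expect_false(qe$usable)

  expect_error(quartileSplit(v8[1:5]), ">= 8")
})

test_that("screen passes planted diagnostic+prognostic genes and rejects nulls", {
  cfg <- smallSynthConfig(seed = 41)
  co <- simulateCohort(cfg)
  # gene 1: tumour-shifted and hazard-linked by construction
  s <- screenGene(co, "100001")
  expect_true(s@passes)
  expect_equal(s@diag_direction, "tumour_higher")
  expect_equal(s@worse_group, "high")
  expect_lt(s@diag_p, 0.05)
  expect_lt(s@logrank_p, 0.05)
  # reruns are bit-identical
  s2 <- screenGene(co, "100001")
  expect_identical(s@diag_p, s2@diag_p)
  expect_identical(s@logrank_p, s2@logrank_p)

  # a flat null gene should not pass
  null_screens <- screenGenes(co, as.character(100200 + 1:20))
  expect_lte(sum(null_screens$passes), 1)

  # constant gene: unscreenable with a reason, carried not dropped
  mat <- expressionMatrix(co)
  mat["G300|100300", ] <- 1
  coc <- StageCohort(mat, sampleInfo(co), methylation = methylationMatrix(co),
                     cohort = "SYNTH")
  sc <- screenGene(coc, "100300")
  expect_false(sc@passes)
  expect_match(sc@reason, "quartile|split")
})

test_that("identical survival in both arms yields p = 1 and no pass", {
  set.seed(42)
  n <- 40
  expr <- rbind("HUB|1" = exp(rnorm(2 * n)), "G|2" = exp(c(rnorm(n), rnorm(n, 2))))
  colnames(expr) <- sprintf("SYNT-0%d-%04d-%s", rep(1:2, each = n), rep(1:n, 2),
                            rep(c("11A", "01A"), each = n))
  tissue <- rep(c("normal", "tumour"), each = n)
  # every tumour sample has the same follow-up record
  ann <- data.frame(barcode = colnames(expr), cohort = "T", tissue = tissue,
                    stage = rep(c("N", "S1"), each = n),
                    time_days = ifelse(tissue == "tumour", 100, NA),
                    event = tissue == "tumour",
                    surv_ok = tissue == "tumour")
  co <- StageCohort(expr, ann, cohort = "T")
  s <- screenGene(co, "2")
  expect_equal(s@logrank_p, 1)
  expect_false(s@passes)
  expect_equal(s@worse_group, "none")
})

test_that("percent-DE reporting rounds half-to-even at two decimals", {
  expect_equal(percentDE(40, 104), 38.46)
  expect_equal(percentDE(84, 421), 19.95)
  expect_equal(percentDE(77, 869), 8.86)
  expect_equal(percentDE(0, 57), 0)
  expect_equal(percentDE(57, 57), 100)
  expect_error(percentDE(1, 0), "positive")
  expect_error(percentDE(5, 4), "de_count")

  # pooled tumour-vs-normal DE filter marks planted shifts
  cfg <- smallSynthConfig(seed = 43)
  co <- simulateCohort(cfg)
  pd <- percentDEGenes(co, as.character(100001:100010))  # de_genes = 1:10
  expect_equal(pd$n_de, 10L)
  pd0 <- percentDEGenes(co, as.character(100200 + 1:20)) # unshifted genes
  expect_lte(pd0$n_de, 2L)
})
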