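test_that("generation is deterministic given config and seed", {
  cfg <- syntheticConfig(nPanel = 800, nCausal = 40, ldBlockSize = 3, seed = 9)
  p1 <- generatePanel(cfg); p2 <- generatePanel(cfg)
  expect_identical(snpData(p1$snps), snpData(p2$snps))
  expect_identical(assignments(p1$annotations), assignments(p2$annotations))
  expect_identical(p1$ld, p2$ld)
  s1 <- simulateGwas(p1); s2 <- simulateGwas(p2)
  expect_identical(snpData(s1$snps), snpData(s2$snps))
  expect_identical(s1$causal, s2$causal)

  # a different seed changes the draw
  p3 <- generatePanel(syntheticConfig(nPanel = 800, nCausal = 40,
                                      ldBlockSize = 3, seed = 10))
  expect_false(identical(snpMaf(p1$snps), snpMaf(p3$snps)))
})

test_that("category rates and LD structure are realised as configured", {
  cfg <- syntheticConfig(nPanel = 1e5, nCausal = 100, ldBlockSize = 4,
                         r2Within = 0.9, seed = 21)
  panel <- generatePanel(cfg)
  for (cat in names(cfg$categoryRates)) {
    r <- cfg$categoryRates[[cat]]
    obs <- length(annotatedIds(panel$annotations, cat)) / cfg$nPanel
    expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / cfg$nPanel))
  }
  expect_true(all(panel$ld$r2 == 0.9))
  # a full block yields choose(4, 2) = 6 pairs
  first_block <- snpIds(panel$snps)[1:4]
  expect_equal(sum(panel$ld$snp_a %in% first_block &
                     panel$ld$snp_b %in% first_block), 6)

  # rate 0 -> category absent
  cfg0 <- syntheticConfig(nPanel = 500, nCausal = 10,
                          categoryRates = c(a = 0, b = 0.2),
                          trueEnrichment = c(a = 2, b = 2), seed = 1)
  p0 <- generatePanel(cfg0)
  expect_length(annotatedIds(p0$annotations, "a"), 0)
})

test_that("null simulation is calibrated: uniform p-values, no enrichment", {
  cfg <- syntheticConfig(nPanel = 2e4, nCausal = 500, effectMean = 0,
                         trueEnrichment = c(cis_eQTL_openchrom = 1,
                                            nsSNP = 1, promoter = 1),
                         ldBlockSize = 1, seed = 77)
  sim <- simulateGwas(generatePanel(cfg))
  p <- pAssoc(sim$snps)
  # with no effects anywhere, hit counts track the threshold
  for (thr in c(0.01, 0.001)) {
    expect_lt(abs(sum(p < thr) - cfg$nPanel * thr),
              4 * sqrt(cfg$nPanel * thr))
  }
  # causal draw is uniform: estimated BF near 1
  panel <- generatePanel(cfg)
  for (cat in names(cfg$categoryRates)) {
    ann <- annotatedIds(panel$annotations, cat)
    est <- estimateBfAnnot(sum(sim$causal %in% ann), cfg$nCausal,
                           length(ann), cfg$nPanel, cat)
    expect_lt(abs(log(bfValue(est))), 3 * logBfSE(est))
  }
})

test_that("the enrichment test rejects at its nominal rate under the null", {
  # 200 replicates of a null comparison: uniform hits vs their own panel
  n_panel <- 4000; n_hit <- 150; rate <- 0.25
  rej <- withr::with_seed(55, {
    vapply(1:200, function(i) {
      annotated <- sample(n_panel, round(rate * n_panel))
      hits <- sample(n_panel, n_hit)
      r <- enrichmentTestCounts(sum(hits %in% annotated), n_hit,
                                length(annotated), n_panel)
      r$p_value < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Table 1 fixture carries the published counts coherently", {
  f <- makeTable1Fixture()
  expect_equal(f$hits$hindorff$nsSNP, 166)
  expect_equal(f$panel$total, 961605)
  expect_equal(round(100 * f$panel$nsSNP / f$panel$total, 1), 3.9)
  expect_equal(round(100 * f$hits$hindorff$cis_eQTL_openchrom /
                       f$hits$hindorff$total, 1), 3.8)
  expect_equal(round(100 * f$hits$johnson$promoter /
                       f$hits$johnson$total, 1), 5.6)
  expect_equal(f$n_tests, 36)
})

test_that("synthetic inputs round-trip through the file readers", {
  cfg <- syntheticConfig(nPanel = 200, nCausal = 20, ldBlockSize = 2,
                         seed = 12)
  panel <- generatePanel(cfg)
  sim <- simulateGwas(panel)
  dir <- tempfile()
  paths <- writeSyntheticInputs(sim, panel, dir)
  back <- readAssocTable(paths[["assoc"]])
  expect_equal(length(back), 200)
  expect_equal(readLdPairs(paths[["ld"]]), panel$ld)
  expect_setequal(readSnpList(paths[["panel"]]), snpIds(panel$snps))
})

test_that("configs are validated", {
  expect_error(syntheticConfig(nPanel = 10, nCausal = 20),
               class = "annotBF_usage_error")
  expect_error(syntheticConfig(categoryRates = c(a = 0.5),
                               trueEnrichment = c(a = 3)),
               "rho", class = "annotBF_usage_error")
  expect_error(syntheticConfig(categoryRates = c(a = 0.1),
                               trueEnrichment = c(b = 2)),
               class = "annotBF_usage_error")
})
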