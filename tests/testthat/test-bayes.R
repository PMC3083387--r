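test_that("estimateBfAnnot is the ratio of annotation proportions", {
  e <- estimateBfAnnot(46, 1219, 7791, 961605)
  expect_equal(bfValue(e), (46 / 1219) / (7791 / 961605))
  expect_equal(logBfSE(e),
               sqrt(1 / 46 - 1 / 1219 + 1 / 7791 - 1 / 961605))

  # equal proportions -> exactly 1
  expect_equal(bfValue(estimateBfAnnot(5, 100, 50, 1000)), 1)

  # zero annotated hits -> bf 0, SE undefined
  e0 <- estimateBfAnnot(0, 100, 10, 1000)
  expect_equal(bfValue(e0), 0)
  expect_true(is.na(logBfSE(e0)))

  expect_error(estimateBfAnnot(5, 100, 0, 1000), "k_panel",
               class = "annotBF_usage_error")
  expect_error(estimateBfAnnot(101, 100, 10, 1000),
               class = "annotBF_usage_error")
})

test_that("a hit set identical to the panel gives BF exactly 1", {
  cfg <- syntheticConfig(nPanel = 500, nCausal = 10, ldBlockSize = 1, seed = 2)
  panel <- generatePanel(cfg)
  for (cat in categories(panel$annotations)) {
    k <- length(annotatedIds(panel$annotations, cat))
    expect_identical(bfValue(estimateBfAnnot(k, 500, k, 500, cat)), 1)
  }
})

test_that("the Haldane option smooths the zero-numerator case", {
  eh <- estimateBfAnnot(0, 100, 10, 1000, haldane = TRUE)
  expect_equal(bfValue(eh), (0.5 / 101) / (10.5 / 1001))
  expect_false(is.na(logBfSE(eh)))
})

test_that("bfNoAnnotation reproduces the percentage ratio", {
  expect_equal(round(bfNoAnnotation(87.6, 94.5), 2), 0.93)
  expect_equal(round(bfNoAnnotation(88.3, 94.5), 2), 0.93)  # 0.9344 by hand
  expect_equal(bfNoAnnotation(94.5, 94.5), 1)
})

test_that("wakefieldAbf equals the normal density ratio on a grid", {
  beta <- seq(-0.8, 0.8, length.out = 10)
  ses <- seq(0.05, 0.5, length.out = 10)
  Ws <- c(0.01, 0.0428, 0.1, 0.5, 1)
  for (se in ses) for (W in Ws) {
    got <- wakefieldAbf(beta, se, W)
    oracle <- dnorm(beta, 0, sqrt(se^2 + W)) / dnorm(beta, 0, se)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # z = 0 closed form
  expect_equal(wakefieldAbf(0, 1, 1), sqrt(1 / 2))
  # W -> 0: prior collapses onto the null, BF -> 1
  expect_equal(wakefieldAbf(0.3, 0.1, 1e-12), 1, tolerance = 1e-6)
  expect_error(wakefieldAbf(0.1, 0), class = "annotBF_usage_error")
})

test_that("wakefieldAbf is strictly increasing in |z| at fixed V and W", {
  z <- seq(0, 8, by = 0.5)
  se <- 0.1
  bf <- wakefieldAbf(z * se, se, W = 0.0428)
  expect_true(all(diff(bf) > 0))
  expect_equal(wakefieldAbf(-0.3, se), wakefieldAbf(0.3, se))  # symmetric
  # log form agrees
  expect_equal(log(bf), wakefieldAbf(z * se, se, W = 0.0428, log = TRUE))
})

test_that("wakefieldPriorW encodes the odds-ratio prior interval", {
  expect_equal(wakefieldPriorW(1.5), (log(1.5) / qnorm(0.975))^2)
})

test_that("assignBfAnnot applies the max-BF rule with a default for none", {
  annot <- AnnotationSet(snp_id = c("rs1", "rs1", "rs2"),
                         category = c("nsSNP", "promoter", "promoter"),
                         provenance = "direct")
  tab <- c(nsSNP = 3.5, promoter = 2.5)
  got <- assignBfAnnot(c("rs1", "rs2", "rs3"), annot, tab, bfDefault = 0.93)
  expect_equal(got$bf_annot, c(3.5, 2.5, 0.93))
  expect_equal(got$applied_category, c("nsSNP", "promoter", "none"))

  # unknown category in the assignments -> configuration error naming it
  bad <- AnnotationSet("rs1", "mystery", "direct")
  expect_error(assignBfAnnot("rs1", bad, tab), "mystery",
               class = "annotBF_usage_error")
})

test_that("recommendedBfTable exposes the supported ranges", {
  lo <- recommendedBfTable("low"); hi <- recommendedBfTable("high")
  expect_equal(as.numeric(lo), c(3.1, 2.9, 1.8))
  expect_equal(as.numeric(hi), c(4.7, 3.5, 2.5))
  expect_equal(as.numeric(recommendedBfTable("mid")),
               (as.numeric(lo) + as.numeric(hi)) / 2)
  expect_equal(attr(lo, "no_annotation"), 0.93)
})

test_that("combinePosterior multiplies prior odds and both Bayes Factors", {
  expect_equal(combinePosterior(1e-5, 1, 1), 1e-5)
  expect_equal(combinePosterior(1e-5, 4, 1e4), 0.4)
  withr::with_seed(99, {
    x <- runif(20, 0.1, 10); y <- runif(20, 0.1, 10)
  })
  expect_equal(combinePosterior(1, x, y), x * y)
  expect_error(combinePosterior(-1, 1, 1), class = "annotBF_usage_error")
})

test_that("estimateBfAnnot recovers a known enrichment on synthetic data", {
  cfg <- syntheticConfig(nPanel = 4e4, nCausal = 1200, effectMean = 0.35,
                         se = 0.05, ldBlockSize = 1, seed = 31)
  panel <- generatePanel(cfg)
  sim <- simulateGwas(panel)
  hits <- names(which(pAssoc(sim$snps) < 1e-5))
  for (cat in names(cfg$categoryRates)) {
    ann <- annotatedIds(panel$annotations, cat)
    est <- estimateBfAnnot(sum(hits %in% ann), length(hits),
                           length(ann), cfg$nPanel, cat)
    expect_lt(abs(log(bfValue(est)) - log(cfg$trueEnrichment[[cat]])),
              3 * logBfSE(est))
  }
})

test_that("posteriorTable combines association and annotation evidence", {
  snps <- SnpSet(c("a", "b", "c"), chrom = "1", pos = 1:3 * 100,
                 beta_hat = c(0.3, 0.3, 0.05), se = 0.1)
  annot <- AnnotationSet("b", "nsSNP", "direct")
  pt <- posteriorTable(snps, annot, bfTable = c(nsSNP = 3.2),
                       bfDefault = 0.93, oPrior = 1e-5)
  expect_equal(pt$o_post, 1e-5 * pt$bf_annot * pt$bf_assoc)
  expect_equal(pt$score, pt$bf_annot * pt$bf_assoc)
  # same association evidence: the annotated SNP ranks ahead after weighting
  expect_lt(pt$rank_after[pt$snp_id == "b"], pt$rank_after[pt$snp_id == "a"])
  # omitting the prior keeps ranks, drops absolute odds
  pt2 <- posteriorTable(snps, annot, bfTable = c(nsSNP = 3.2))
  expect_true(all(is.na(pt2$o_post)))
  expect_equal(pt2$rank_after, pt$rank_after)
})
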