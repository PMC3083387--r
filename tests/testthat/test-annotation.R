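test_that("annotateById assigns exactly the listed SNPs, directly", {
  s <- SnpSet(paste0("rs", 1:5), chrom = "1", pos = 1:5 * 100)
  a <- annotateById(s, c("rs2", "rs4", "rs99"), "nsSNP")
  expect_equal(sort(annotatedIds(a, "nsSNP")), c("rs2", "rs4"))
  expect_true(all(assignments(a)$provenance == "direct"))
  expect_length(annotateById(s, character(0), "nsSNP"), 0)
})

test_that("annotateByPosition honours the half-open boundary and dedups", {
  s <- SnpSet(c("rsA", "rsB"), chrom = "1", pos = c(100, 99))
  iv <- readBedIntervals(tmpLines("chr1\t99\t200"), "promoter")
  a <- annotateByPosition(s, iv)
  expect_equal(annotatedIds(a, "promoter"), "rsA")  # pos 100 in, pos 99 out

  # two overlapping intervals of the same category -> single assignment
  iv2 <- c(iv, readBedIntervals(tmpLines("chr1\t50\t150"), "promoter"))
  expect_equal(length(annotateByPosition(s["rsA"], iv2)), 1)
})

test_that("annotateByPosition agrees with a brute-force scan", {
  for (seed in c(11, 12, 13)) {
    withr::with_seed(seed, {
      n_snp <- 80; n_iv <- 60
      chrom <- sample(c("chr1", "chr2", "chr3"), n_snp, replace = TRUE)
      pos <- sample(1:5000, n_snp)
      ivc <- sample(c("chr1", "chr2", "chr3"), n_iv, replace = TRUE)
      st <- sample(0:4900, n_iv)
      en <- st + sample(1:100, n_iv, replace = TRUE)
    })
    s <- SnpSet(sprintf("s%03d", 1:n_snp), chrom, pos)
    f <- tmpLines(paste(ivc, st, en, sep = "\t"))
    got <- annotatedIds(annotateByPosition(s, readBedIntervals(f, "cat")), "cat")
    want <- snpIds(s)[bruteOverlap(chrom, pos, ivc, st, en)]
    expect_setequal(got, want)
  }
})

test_that("classifyCisEqtl uses an inclusive 200 kb bound", {
  expect_equal(classifyCisEqtl("1", 1e6, "1", 1e6 + 200000), "cis")
  expect_equal(classifyCisEqtl("1", 1e6, "1", 1e6 + 200001), "trans")
  expect_equal(classifyCisEqtl("1", 1e6, "2", 1e6), "trans")
  expect_equal(classifyCisEqtl("chr1", 500, "1", 600), "cis")
})

test_that("selectEqtls filters by rank, cis status and open chromatin", {
  # 6 eQTLs: ranks 1..6; 3 cis; of those, 2 in open chromatin
  snps <- SnpSet(paste0("e", 1:6), chrom = c("1", "1", "1", "2", "2", "3"),
                 pos = c(1000, 2000, 300000, 1000, 5e6, 1000))
  eq <- data.frame(snp_id = paste0("e", 1:6),
                   transcript_chrom = c("1", "1", "1", "2", "2", "4"),
                   transcript_pos = c(1500, 100000, 10000, 150000, 1e6, 1000),
                   eqtl_rank = 1:6)
  # cis: e1 (500 bp), e2 (98 kb), e4 (149 kb); trans: e3 (290 kb), e5, e6
  expect_setequal(selectEqtls(eq, maxRank = 6, cisOnly = TRUE, snps = snps),
                  c("e1", "e2", "e4"))
  # open chromatin covers e1 and e4 only
  oc <- readBedIntervals(tmpLines(c("chr1\t900\t1100", "chr2\t500\t1500")), "oc")
  expect_setequal(
    selectEqtls(eq, 6, cisOnly = TRUE, openChromatin = oc, snps = snps),
    c("e1", "e4"))
  # rank cut before any other filter
  expect_length(selectEqtls(eq, maxRank = 5, cisOnly = FALSE), 5)
  expect_length(selectEqtls(eq[eq$snp_id %in% c("e3", "e5", "e6"), ],
                            6, cisOnly = TRUE, snps = snps), 0)
})

test_that("propagateLdProxies is single-hop with an inclusive threshold", {
  snps <- SnpSet(c("rs1", "rs2", "rs3"), chrom = "1", pos = c(100, 200, 300))
  direct <- annotateById(snps, "rs1", "nsSNP")
  ld <- data.frame(snp_a = c("rs2", "rs3"), snp_b = c("rs1", "rs2"),
                   r2 = c(0.85, 0.9))
  a <- propagateLdProxies(direct, ld, snps)
  d <- assignments(a)
  expect_setequal(annotatedIds(a, "nsSNP"), c("rs1", "rs2"))
  expect_equal(d$proxy_source[d$snp_id == "rs2"], "rs1")
  # rs3 links only to the proxy-annotated rs2: no transitive propagation
  expect_false("rs3" %in% annotatedIds(a, "nsSNP"))

  # exactly at threshold counts; just below does not
  ld2 <- data.frame(snp_a = "rs2", snp_b = "rs1", r2 = 0.8)
  expect_true("rs2" %in% annotatedIds(propagateLdProxies(direct, ld2, snps), "nsSNP"))
  ld3 <- data.frame(snp_a = "rs2", snp_b = "rs1", r2 = 0.79)
  expect_false("rs2" %in% annotatedIds(propagateLdProxies(direct, ld3, snps), "nsSNP"))
})

test_that("LD propagation is idempotent and monotone in the threshold", {
  cfg <- syntheticConfig(nPanel = 300, nCausal = 10, ldBlockSize = 3,
                         r2Within = 0.85, seed = 5)
  panel <- generatePanel(cfg)
  once <- propagateLdProxies(panel$annotations, panel$ld, panel$snps)
  twice <- propagateLdProxies(once, panel$ld, panel$snps)
  expect_identical(assignments(once), assignments(twice))
  expect_gte(length(once), length(panel$annotations))

  # raising r2Min never adds assignments
  sizes <- vapply(c(0.5, 0.8, 0.86, 1), function(t) {
    length(propagateLdProxies(panel$annotations, panel$ld, panel$snps,
                              r2Min = t))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("every ld_proxy assignment points at a direct source in its category", {
  cfg <- syntheticConfig(nPanel = 400, nCausal = 10, ldBlockSize = 4,
                         r2Within = 0.9, seed = 8)
  panel <- generatePanel(cfg)
  a <- assignments(propagateLdProxies(panel$annotations, panel$ld, panel$snps))
  prox <- a[a$provenance == "ld_proxy", ]
  direct <- a[a$provenance == "direct", ]
  ok <- mapply(function(src, cat) {
    any(direct$snp_id == src & direct$category == cat)
  }, prox$proxy_source, prox$category)
  expect_true(all(ok))
})

test_that("uniqueAnnotationSubset drops multiply annotated SNPs everywhere", {
  a <- AnnotationSet(snp_id = c("rs1", "rs1", "rs2", "rs3", "rs4"),
                     category = c("nsSNP", "promoter", "nsSNP", "promoter",
                                  "promoter"),
                     provenance = c("direct", "direct", "direct", "ld_proxy",
                                    "direct"),
                     proxy_source = c("", "", "", "rs9", ""))
  u <- uniqueAnnotationSubset(a)
  expect_false("rs1" %in% u$nsSNP)        # multiply annotated: out of both
  expect_false("rs1" %in% u$promoter)
  expect_setequal(u$nsSNP, "rs2")
  expect_setequal(u$promoter, c("rs3", "rs4"))  # proxy-only assignment kept
})

test_that("direct provenance wins when merging assignments", {
  a1 <- AnnotationSet("rs1", "nsSNP", "ld_proxy", "rs2")
  a2 <- AnnotationSet("rs1", "nsSNP", "direct", "")
  m <- c(a1, a2)
  expect_equal(length(m), 1)
  expect_equal(assignments(m)$provenance, "direct")
})
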