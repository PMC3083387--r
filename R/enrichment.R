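#' Bonferroni-corrected per-test thresholds
#'
#' @param nTests number of comparisons in the family.
#' @param levels family-wise significance levels.
#' @return named numeric vector of per-test thresholds `level / nTests`.
#' @examples
#' bonferroniThresholds(36)  # 2.8e-05 2.8e-04 1.4e-03 at 2 sig. figures
#' @export
bonferroniThresholds <- function(nTests, levels = c(0.001, 0.01, 0.05)) {
  if (nTests < 1) .stopUsage("nTests must be >= 1")
  setNames(levels / nTests, as.character(levels))
}

## Core of the enrichment comparison, on counts. The panel is treated as a
## fixed (effectively error-free) background, so the null SE uses the panel
## proportion with the hit-set size: binomial variation in the hits only.
.enrichCounts <- function(kHit, nHit, kPanel, nPanel, category, nTests,
                          levels = c(0.001, 0.01, 0.05)) {
  if (nHit < 1 || nPanel < 1) .stopUsage("nHit and nPanel must be >= 1")
  if (kHit > nHit || kPanel > nPanel) .stopUsage("counts exceed set sizes")
  if (nTests < 1) .stopUsage("nTests must be >= 1")
  p_hit <- kHit / nHit
  p_panel <- kPanel / nPanel
  if (p_panel <= 0 || p_panel >= 1)
    .stopUsage("degenerate null: panel proportion must lie strictly in (0, 1)")
  se_hit <- sqrt(p_hit * (1 - p_hit) / nHit)
  z <- (p_hit - p_panel) / sqrt(p_panel * (1 - p_panel) / nHit)
  p_value <- 2 * pnorm(-abs(z))
  thr <- bonferroniThresholds(nTests, levels)
  passed <- levels[p_value < thr]
  tier <- if (length(passed)) as.character(min(passed)) else "none"
  data.frame(category = category, n_hit = nHit, k_hit = kHit,
             n_panel = nPanel, k_panel = kPanel,
             p_hit = p_hit, p_panel = p_panel, se_hit = se_hit,
             z = z, p_value = p_value, tier = tier,
             stringsAsFactors = FALSE)
}

#' Hit-vs-panel annotation enrichment test
#'
#' Compares the proportion of annotated SNPs in a hit set against a panel
#' background with a normal-approximation z-test. The panel counts are large
#' enough that their sampling error is negligible, so the null standard error
#' uses the panel proportion with the hit-set size
#' (`z = (p_hit - p_panel) / sqrt(p_panel (1 - p_panel) / n_hit)`); the
#' reported `se_hit` error bar is the binomial SE of the hit proportion.
#' P-values are two-sided; the significance `tier` is the most stringent
#' family-wise level in `{0.001, 0.01, 0.05}` passed after Bonferroni
#' correction over `nTests` comparisons.
#'
#' @param hitIds,panelIds character vectors of SNP ids (duplicates ignored).
#' @param annotated character vector of annotated SNP ids.
#' @param category category label for the output row.
#' @param nTests number of comparisons in the Bonferroni family (default 1).
#' @return one-row data.frame: counts, proportions, `se_hit`, `z`,
#'   `p_value`, `tier`.
#' @seealso [enrichmentTestCounts()] when only the counts are available.
#' @export
enrichmentTest <- function(hitIds, panelIds, annotated,
                           category = "annotation", nTests = 1) {
  hitIds <- unique(hitIds)
  panelIds <- unique(panelIds)
  .enrichCounts(sum(hitIds %in% annotated), length(hitIds),
                sum(panelIds %in% annotated), length(panelIds),
                category, nTests)
}

#' @rdname enrichmentTest
#' @param kHit,nHit annotated / total counts in the hit set.
#' @param kPanel,nPanel annotated / total counts in the panel.
#' @export
enrichmentTestCounts <- function(kHit, nHit, kPanel, nPanel,
                                 category = "annotation", nTests = 1) {
  .enrichCounts(kHit, nHit, kPanel, nPanel, category, nTests)
}

#' Stratify SNPs by minor allele frequency
#'
#' Splits SNP ids at a MAF cutoff: `low` is `maf < cutoff`, `high` is
#' `maf >= cutoff` (the cutoff itself falls in the high stratum). SNPs with
#' missing MAF go to neither stratum and are returned separately.
#'
#' @param snps a [SnpSet-class].
#' @param cutoff MAF cutoff in `(0, 0.5]` (default 0.1).
#' @return list with character vectors `low`, `high`, `missing`.
#' @export
stratifyByMaf <- function(snps, cutoff = 0.1) {
  if (cutoff <= 0 || cutoff > 0.5) .stopUsage("cutoff must lie in (0, 0.5]")
  d <- snpData(snps)
  list(low = d$snp_id[!is.na(d$maf) & d$maf < cutoff],
       high = d$snp_id[!is.na(d$maf) & d$maf >= cutoff],
       missing = d$snp_id[is.na(d$maf)])
}

#' Bayes-Factor sweep over hit-definition thresholds
#'
#' Re-estimates the annotation Bayes Factor of each category while tightening
#' the p-value threshold that defines the hit set (`p_assoc < cutoff`,
#' strict). When the pool of candidate hits is a mixture of true and false
#' associations, more stringent thresholds enrich for true hits and the Bayes
#' Factors rise. Cutoffs where the hit set is empty are reported with `NA`
#' Bayes Factors rather than an error.
#'
#' @param snps a [SnpSet-class] with `p_assoc` for the candidate hit SNPs.
#' @param annotated named list of character vectors: per-category annotated
#'   SNP ids.
#' @param panelIds character vector of panel (background) SNP ids.
#' @param cutoffs numeric p-value thresholds, ordered least to most
#'   stringent.
#' @return data.frame with one row per (cutoff, category): `cutoff`,
#'   `category`, `n_hit`, `k_hit`, `k_panel`, `n_panel`, `bf`, `log_bf_se`.
#' @export
thresholdSweep <- function(snps, annotated, panelIds, cutoffs) {
  if (is.null(names(annotated)) || any(!nzchar(names(annotated))))
    .stopUsage("annotated must be a named list of id vectors")
  if (is.unsorted(rev(cutoffs), strictly = TRUE))
    .stopUsage("cutoffs must be sorted from least to most stringent")
  p <- pAssoc(snps)
  if (anyNA(p)) .stopUsage("every candidate hit SNP needs a p_assoc")
  panelIds <- unique(panelIds)
  n_panel <- length(panelIds)
  rows <- list()
  for (cut in cutoffs) {
    hit_ids <- names(p)[p < cut]
    for (cat in names(annotated)) {
      k_panel <- sum(panelIds %in% annotated[[cat]])
      n_hit <- length(hit_ids)
      k_hit <- sum(hit_ids %in% annotated[[cat]])
      if (n_hit == 0 || k_panel == 0) {
        bf <- NA_real_; lse <- NA_real_
      } else {
        est <- estimateBfAnnot(k_hit, n_hit, k_panel, n_panel, category = cat)
        bf <- bfValue(est); lse <- logBfSE(est)
      }
      rows[[length(rows) + 1]] <- data.frame(
        cutoff = cut, category = cat, n_hit = n_hit, k_hit = k_hit,
        k_panel = k_panel, n_panel = n_panel, bf = bf, log_bf_se = lse,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
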