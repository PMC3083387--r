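#' Empirical annotation Bayes Factor
#'
#' Estimates `BF_annot` for one category as the proportion of annotated SNPs
#' in the hit set divided by the proportion in the panel (background) set.
#' Since hits are a vanishing fraction of all panel SNPs, the unselected
#' panel stands in for the non-hit set. The standard error of `log(BF)` is
#' the usual delta-method expression for a ratio of binomial proportions,
#' `sqrt(1/k_hit - 1/n_hit + 1/k_panel - 1/n_panel)`, undefined when
#' `k_hit = 0` (in which case `bf = 0` is returned as-is; set
#' `haldane = TRUE` for a +0.5-per-cell smoothed estimate instead).
#'
#' @param kHit,nHit annotated / total counts in the hit set.
#' @param kPanel,nPanel annotated / total counts in the panel.
#' @param category category label carried into the result.
#' @param haldane apply the Haldane-style continuity correction (+0.5 to each
#'   annotated count, +1 to each total); off by default — the raw ratio is
#'   the canonical estimator.
#' @return a [BayesFactorEstimate-class].
#' @examples
#' bfValue(estimateBfAnnot(46, 1219, 7791, 961605))  # ~4.66
#' @export
estimateBfAnnot <- function(kHit, nHit, kPanel, nPanel,
                            category = "annotation", haldane = FALSE) {
  if (nHit < 1 || nPanel < 1) .stopUsage("set sizes must be >= 1")
  if (kHit > nHit || kPanel > nPanel)
    .stopUsage("annotated counts cannot exceed set sizes")
  if (kHit < 0 || kPanel < 0) .stopUsage("counts must be non-negative")
  if (haldane) {
    bf <- ((kHit + 0.5) / (nHit + 1)) / ((kPanel + 0.5) / (nPanel + 1))
    lse <- sqrt(1 / (kHit + 0.5) - 1 / (nHit + 1) +
                  1 / (kPanel + 0.5) - 1 / (nPanel + 1))
  } else {
    if (kPanel == 0)
      .stopUsage("k_panel = 0: panel proportion is zero, BF undefined")
    bf <- (kHit / nHit) / (kPanel / nPanel)
    lse <- if (kHit > 0) {
      sqrt(1 / kHit - 1 / nHit + 1 / kPanel - 1 / nPanel)
    } else NA_real_
  }
  new("BayesFactorEstimate", category = category,
      k_hit = as.numeric(kHit), n_hit = as.numeric(nHit),
      k_panel = as.numeric(kPanel), n_panel = as.numeric(nPanel),
      bf = bf, log_bf_se = lse)
}

#' Bayes Factor for SNPs without annotation
#'
#' The ratio of the unannotated percentage among hit SNPs to that among
#' panel SNPs — slightly below 1, since annotation is over-represented among
#' hits. Accepts the percentages as printed (e.g. 87.6 and 94.5).
#'
#' @param unannotHitPct percentage of hit SNPs with no annotation, in
#'   `(0, 100]`.
#' @param unannotPanelPct percentage of panel SNPs with no annotation.
#' @return the ratio (numeric scalar).
#' @examples
#' bfNoAnnotation(87.6, 94.5)  # ~0.93
#' @export
bfNoAnnotation <- function(unannotHitPct, unannotPanelPct) {
  if (unannotHitPct <= 0 || unannotHitPct > 100 ||
      unannotPanelPct <= 0 || unannotPanelPct > 100)
    .stopUsage("percentages must lie in (0, 100]")
  unannotHitPct / unannotPanelPct
}

#' Prior effect variance for the Wakefield Bayes Factor
#'
#' Sets `W` so that the prior 95% interval for the odds ratio is
#' `(1/oddsRatio, oddsRatio)` on the log-odds scale:
#' `W = (log(oddsRatio) / z_{level})^2`. The default (odds ratio 1.5) is a
#' conventional effect-size prior for common-variant GWAS.
#'
#' @param oddsRatio upper bound of the prior odds-ratio interval.
#' @param level coverage of the interval.
#' @return `W`, the prior variance of the log-odds effect.
#' @export
wakefieldPriorW <- function(oddsRatio = 1.5, level = 0.95) {
  if (oddsRatio <= 1) .stopUsage("oddsRatio must exceed 1")
  (log(oddsRatio) / qnorm(1 - (1 - level) / 2))^2
}

#' Wakefield approximate Bayes Factor for association
#'
#' The asymptotic Bayes Factor in favour of association for a log-odds
#' effect estimate `beta_hat` with standard error `se`, under a normal
#' `N(0, W)` effect prior:
#' `BF_assoc = sqrt(V / (V + W)) * exp(z^2 W / (2 (V + W)))` with `V = se^2`
#' and `z = beta_hat / se`. This equals the ratio of the `N(0, V + W)` to the
#' `N(0, V)` density at `beta_hat`, so no integration is needed. At `z = 0`
#' it attains its minimum `sqrt(V / (V + W))`; it is strictly increasing in
#' `|z|`.
#'
#' @param betaHat effect estimate(s), log-odds scale (vectorised).
#' @param se standard error(s), positive.
#' @param W prior effect variance (default [wakefieldPriorW()]).
#' @param log return `log(BF)` instead (safe for extreme `z`).
#' @return numeric vector of Bayes Factors (names kept from `betaHat`).
#' @examples
#' wakefieldAbf(0, se = 1, W = 1)  # sqrt(1/2)
#' @export
wakefieldAbf <- function(betaHat, se, W = wakefieldPriorW(), log = FALSE) {
  if (any(se <= 0)) .stopUsage("se must be > 0")
  if (any(W <= 0)) .stopUsage("W must be > 0")
  V <- se^2
  z <- betaHat / se
  out <- if (log) {
    0.5 * base::log(V / (V + W)) + z^2 * W / (2 * (V + W))
  } else {
    sqrt(V / (V + W)) * exp(z^2 * W / (2 * (V + W)))
  }
  names(out) <- names(betaHat)
  out
}

#' Recommended annotation Bayes-Factor table
#'
#' The empirically supported ranges for the three annotation categories —
#' cis eQTLs in open chromatin 3.1–4.7, non-synonymous SNPs 2.9–3.5,
#' promoter SNPs 1.8–2.5 — with 0.93 for unannotated SNPs. `"mid"` returns
#' midpoints; investigators wanting to strengthen (weaken) the influence of
#' annotation take `"high"` (`"low"`).
#'
#' @param weight `"mid"`, `"low"` or `"high"`.
#' @return named numeric vector over the three categories, with the
#'   no-annotation Bayes Factor in attribute `"no_annotation"`.
#' @export
recommendedBfTable <- function(weight = c("mid", "low", "high")) {
  weight <- match.arg(weight)
  ranges <- list(cis_eQTL_openchrom = c(3.1, 4.7),
                 nsSNP = c(2.9, 3.5),
                 promoter = c(1.8, 2.5))
  pick <- switch(weight,
                 low = vapply(ranges, `[`, 0, 1L),
                 high = vapply(ranges, `[`, 0, 2L),
                 mid = vapply(ranges, mean, 0))
  structure(pick, no_annotation = 0.93)
}

#' Assign a single annotation Bayes Factor per SNP
#'
#' When a SNP carries several annotations (directly or via LD proxy) the
#' category with the largest Bayes Factor is used — the conservative
#' resolution, assuming a second annotation can raise but never lower the
#' evidence. SNPs with no assignment receive `bfDefault` and category
#' `"none"`. Ties between equal Bayes Factors resolve to the first category
#' in `bfTable` order.
#'
#' @param snpIds character vector of SNP ids to score.
#' @param annot an [AnnotationSet-class].
#' @param bfTable named numeric vector: Bayes Factor per category. Every
#'   category assigned to a requested SNP must appear here, else a
#'   configuration error names the missing category.
#' @param bfDefault Bayes Factor for unannotated SNPs (default 0.93).
#' @return data.frame with columns `snp_id`, `bf_annot`, `applied_category`.
#' @export
assignBfAnnot <- function(snpIds, annot, bfTable = recommendedBfTable(),
                          bfDefault = 0.93) {
  if (any(bfTable <= 0) || bfDefault <= 0)
    .stopUsage("Bayes Factors must be > 0")
  d <- assignments(annot)
  d <- d[d$snp_id %in% snpIds, , drop = FALSE]
  missing_cat <- setdiff(unique(d$category), names(bfTable))
  if (length(missing_cat))
    .stopUsage("no Bayes Factor configured for category: ",
               paste(missing_cat, collapse = ", "))
  bf <- rep(bfDefault, length(snpIds))
  cat_used <- rep("none", length(snpIds))
  if (nrow(d) > 0) {
    d$bf <- bfTable[d$category]
    # order: per SNP, decreasing BF, ties by bfTable position
    d$pos <- match(d$category, names(bfTable))
    d <- d[order(d$snp_id, -d$bf, d$pos), , drop = FALSE]
    d <- d[!duplicated(d$snp_id), , drop = FALSE]
    idx <- match(d$snp_id, snpIds)
    bf[idx] <- d$bf
    cat_used[idx] <- d$category
  }
  data.frame(snp_id = snpIds, bf_annot = bf, applied_category = cat_used,
             stringsAsFactors = FALSE)
}

#' Posterior odds of true association
#'
#' `O_post = O_prior * BF_annot * BF_assoc`: the prior odds of causality
#' updated by the independent annotation and association evidence.
#'
#' @param oPrior prior odds (e.g. `1e-5`, the conventional genome-wide
#'   value).
#' @param bfAnnot annotation Bayes Factor(s).
#' @param bfAssoc association Bayes Factor(s).
#' @return numeric vector of posterior odds.
#' @export
combinePosterior <- function(oPrior, bfAnnot, bfAssoc) {
  if (any(oPrior <= 0) || any(bfAnnot <= 0) || any(bfAssoc <= 0))
    .stopUsage("oPrior, bfAnnot and bfAssoc must all be > 0")
  oPrior * bfAnnot * bfAssoc
}

#' Per-SNP posterior table
#'
#' Computes, for every SNP with an effect estimate and standard error, the
#' Wakefield `BF_assoc`, the applied `BF_annot` (max-BF rule over the SNP's
#' annotations, `bfDefault` when unannotated), their product, posterior odds
#' when `oPrior` is given, and ranks before (by `BF_assoc`) and after (by
#' the product). When `oPrior` is omitted the `o_post` column is `NA`;
#' relative ranking is unaffected, as the prior multiplies every SNP equally.
#'
#' @param snps a [SnpSet-class] with `beta_hat` and `se`.
#' @param annot an [AnnotationSet-class].
#' @param bfTable named numeric vector of per-category Bayes Factors.
#' @param bfDefault Bayes Factor for unannotated SNPs.
#' @param W Wakefield prior effect variance.
#' @param oPrior prior odds, or `NULL` for ranking-only output.
#' @return data.frame: `snp_id`, `z`, `bf_assoc`, `applied_category`,
#'   `bf_annot`, `score` (= `bf_annot * bf_assoc`), `o_post`, `rank_before`,
#'   `rank_after`.
#' @export
posteriorTable <- function(snps, annot, bfTable = recommendedBfTable(),
                           bfDefault = 0.93, W = wakefieldPriorW(),
                           oPrior = NULL) {
  d <- snpData(snps)
  ok <- !is.na(d$beta_hat) & !is.na(d$se)
  if (!all(ok))
    .stopUsage("all SNPs need beta_hat and se; missing for ",
               sum(!ok), " SNP(s)")
  bfa <- wakefieldAbf(d$beta_hat, d$se, W = W)
  ann <- assignBfAnnot(d$snp_id, annot, bfTable, bfDefault)
  score <- ann$bf_annot * bfa
  out <- data.frame(snp_id = d$snp_id,
                    z = d$beta_hat / d$se,
                    bf_assoc = bfa,
                    applied_category = ann$applied_category,
                    bf_annot = ann$bf_annot,
                    score = score,
                    o_post = if (is.null(oPrior)) NA_real_ else
                      combinePosterior(oPrior, ann$bf_annot, bfa),
                    stringsAsFactors = FALSE)
  out$rank_before <- rankValues(out$bf_assoc)
  out$rank_after <- rankValues(out$score)
  out
}
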