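#' SnpSet: a table of SNPs with positions, frequencies and association results
#'
#' The central container of the package: one row per SNP, holding the
#' identifier, genomic position (1-based), minor allele frequency, the
#' genotyping panels the SNP belongs to, and (optionally) association summary
#' statistics — a p-value, a log-odds effect estimate and its standard error.
#'
#' @slot snps data.frame with columns `snp_id`, `chrom`, `pos`, `maf`,
#'   `p_assoc`, `beta_hat`, `se` and a list-column `panels`.
#'
#' @seealso [SnpSet()] for construction, [readAssocTable()] to read PLINK
#'   association output.
#' @exportClass SnpSet
setClass("SnpSet", representation(snps = "data.frame"))

setValidity("SnpSet", function(object) {
  d <- object@snps
  need <- c("snp_id", "chrom", "pos", "maf", "p_assoc", "beta_hat", "se",
            "panels")
  if (!all(need %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$snp_id))
    return(paste("duplicate snp_id:",
                 paste(unique(d$snp_id[duplicated(d$snp_id)]), collapse = ", ")))
  if (any(d$pos < 1, na.rm = TRUE)) return("pos must be >= 1")
  if (any(d$maf < 0 | d$maf > 0.5, na.rm = TRUE))
    return("maf must lie in [0, 0.5]")
  if (any(d$se <= 0, na.rm = TRUE)) return("se must be > 0 when present")
  if (any(d$p_assoc <= 0 | d$p_assoc > 1, na.rm = TRUE))
    return("p_assoc must lie in (0, 1]")
  if (!is.list(d$panels)) return("panels must be a list column")
  TRUE
})

#' Construct a SnpSet
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels (`"1"` and `"chr1"` are treated as equal in
#'   positional filters).
#' @param pos 1-based base-pair positions.
#' @param maf minor allele frequencies in `[0, 0.5]`, `NA` when unknown.
#' @param p_assoc association p-values in `(0, 1]`, `NA` when unknown.
#' @param beta_hat effect estimates on the log-odds scale, `NA` when unknown.
#' @param se standard errors of `beta_hat` (positive), `NA` when unknown.
#' @param panels list of character vectors naming the panels each SNP is on;
#'   a single character vector is recycled to all SNPs.
#' @return A [SnpSet-class] object.
#' @examples
#' s <- SnpSet(c("rs1", "rs2"), chrom = c("1", "6"), pos = c(1000, 26e6))
#' length(s)
#' @export
SnpSet <- function(snp_id, chrom, pos, maf = NA_real_, p_assoc = NA_real_,
                   beta_hat = NA_real_, se = NA_real_, panels = NULL) {
  n <- length(snp_id)
  if (is.null(panels)) {
    panels <- rep(list(character(0)), n)
  } else if (is.character(panels)) {
    panels <- rep(list(panels), n)
  }
  d <- data.frame(snp_id = as.character(snp_id),
                  chrom = as.character(chrom),
                  pos = as.numeric(pos),
                  maf = rep_len(as.numeric(maf), n),
                  p_assoc = rep_len(as.numeric(p_assoc), n),
                  beta_hat = rep_len(as.numeric(beta_hat), n),
                  se = rep_len(as.numeric(se), n),
                  stringsAsFactors = FALSE)
  d$panels <- panels
  new("SnpSet", snps = d)
}

#' @describeIn SnpSet number of SNPs
#' @param x a `SnpSet`
#' @export
setMethod("length", "SnpSet", function(x) nrow(x@snps))

setMethod("show", "SnpSet", function(object) {
  d <- object@snps
  cat("SnpSet with", nrow(d), "SNPs\n")
  cat("  with MAF:", sum(!is.na(d$maf)),
      "| with p-value:", sum(!is.na(d$p_assoc)),
      "| with beta/se:", sum(!is.na(d$beta_hat) & !is.na(d$se)), "\n")
  if (nrow(d) > 0) {
    cat("  head:", paste(head(d$snp_id, 5), collapse = ", "),
        if (nrow(d) > 5) "..." else "", "\n")
  }
})

#' Subset a SnpSet
#'
#' @param x a `SnpSet`
#' @param i integer, logical, or character (SNP id) index
#' @param j,...,drop ignored
#' @export
setMethod("[", "SnpSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@snps$snp_id)
    if (anyNA(idx))
      .stopUsage("unknown snp_id: ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  d <- x@snps[i, , drop = FALSE]
  rownames(d) <- NULL
  new("SnpSet", snps = d)
})

#' Accessors for SnpSet columns
#'
#' `snpIds`, `snpChrom`, `snpPos`, `snpMaf`, `pAssoc`, `betaHat`, `snpSe` and
#' `snpPanels` extract the corresponding per-SNP vectors; `snpData` returns
#' the underlying data.frame.
#'
#' @param x a [SnpSet-class]
#' @return a vector (or for `snpPanels` a list, for `snpData` a data.frame)
#'   with one element per SNP.
#' @name snp-accessors
NULL

#' @rdname snp-accessors
#' @export
snpIds <- function(x) x@snps$snp_id
#' @rdname snp-accessors
#' @export
snpChrom <- function(x) x@snps$chrom
#' @rdname snp-accessors
#' @export
snpPos <- function(x) x@snps$pos
#' @rdname snp-accessors
#' @export
snpMaf <- function(x) x@snps$maf
#' @rdname snp-accessors
#' @export
pAssoc <- function(x) setNames(x@snps$p_assoc, x@snps$snp_id)
#' @rdname snp-accessors
#' @export
betaHat <- function(x) setNames(x@snps$beta_hat, x@snps$snp_id)
#' @rdname snp-accessors
#' @export
snpSe <- function(x) setNames(x@snps$se, x@snps$snp_id)
#' @rdname snp-accessors
#' @export
snpPanels <- function(x) setNames(x@snps$panels, x@snps$snp_id)
#' @rdname snp-accessors
#' @export
snpData <- function(x) x@snps

#' Represent SNP positions as a GRanges
#'
#' One width-1 range per SNP, used internally for interval containment tests
#' against BED annotation tracks.
#'
#' @param x a [SnpSet-class]
#' @return a [GenomicRanges::GRanges] with metadata column `snp_id`.
#' @export
snpGRanges <- function(x) {
  d <- x@snps
  gr <- GenomicRanges::GRanges(
    seqnames = .normChrom(d$chrom),
    ranges = IRanges::IRanges(start = d$pos, width = 1L))
  S4Vectors::mcols(gr)$snp_id <- d$snp_id
  gr
}

#' AnnotationSet: per-SNP annotation-category assignments with provenance
#'
#' One row per (SNP, category) pair. `provenance` records whether the SNP
#' carries the annotation itself (`"direct"`) or inherits it from a proxy SNP
#' in linkage disequilibrium (`"ld_proxy"`), in which case `proxy_source`
#' names the directly annotated proxy.
#'
#' @slot assignments data.frame with columns `snp_id`, `category`,
#'   `provenance`, `proxy_source`.
#'
#' @seealso [annotateById()], [annotateByPosition()], [propagateLdProxies()].
#' @exportClass AnnotationSet
setClass("AnnotationSet", representation(assignments = "data.frame"))

setValidity("AnnotationSet", function(object) {
  d <- object@assignments
  need <- c("snp_id", "category", "provenance", "proxy_source")
  if (!all(need %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  if (!all(d$provenance %in% c("direct", "ld_proxy")))
    return("provenance must be 'direct' or 'ld_proxy'")
  bad <- d$provenance == "ld_proxy" & (is.na(d$proxy_source) | d$proxy_source == "")
  if (any(bad)) return("ld_proxy assignments must carry a proxy_source")
  if (anyDuplicated(d[, c("snp_id", "category")]))
    return("(snp_id, category) pairs must be unique")
  TRUE
})

## Deduplicate (snp_id, category), direct provenance winning over ld_proxy.
.dedupAssignments <- function(d) {
  if (nrow(d) == 0) return(d)
  d <- d[order(d$snp_id, d$category, d$provenance != "direct"), , drop = FALSE]
  d <- d[!duplicated(d[, c("snp_id", "category")]), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Construct an AnnotationSet
#'
#' Duplicated (SNP, category) pairs are collapsed, direct assignments taking
#' precedence over LD-proxy ones.
#'
#' @param snp_id character vector of SNP ids.
#' @param category annotation category names.
#' @param provenance `"direct"` or `"ld_proxy"` per assignment.
#' @param proxy_source for `ld_proxy` rows, the directly annotated proxy SNP.
#' @return An [AnnotationSet-class].
#' @export
AnnotationSet <- function(snp_id = character(0), category = character(0),
                          provenance = "direct", proxy_source = "") {
  n <- length(snp_id)
  d <- data.frame(snp_id = as.character(snp_id),
                  category = rep_len(as.character(category), n),
                  provenance = rep_len(as.character(provenance), n),
                  proxy_source = rep_len(as.character(proxy_source), n),
                  stringsAsFactors = FALSE)
  new("AnnotationSet", assignments = .dedupAssignments(d))
}

#' @describeIn AnnotationSet number of assignments
#' @param x an `AnnotationSet`
#' @export
setMethod("length", "AnnotationSet", function(x) nrow(x@assignments))

setMethod("show", "AnnotationSet", function(object) {
  d <- object@assignments
  cat("AnnotationSet with", nrow(d), "assignments in",
      length(unique(d$category)), "categories\n")
  if (nrow(d) > 0) {
    tab <- table(d$category, d$provenance)
    print(tab)
  }
})

#' Combine AnnotationSets
#'
#' @param x,... `AnnotationSet` objects
#' @return the merged, deduplicated `AnnotationSet` (direct provenance wins).
#' @export
setMethod("c", "AnnotationSet", function(x, ...) {
  d <- do.call(rbind, lapply(c(list(x), list(...)), assignments))
  new("AnnotationSet", assignments = .dedupAssignments(d))
})

#' Accessors for AnnotationSet
#'
#' `assignments` returns the assignment table; `categories` the distinct
#' category names; `annotatedIds` the SNP ids carrying a given category.
#'
#' @param x an [AnnotationSet-class]
#' @param category a category name; `NULL` for all categories.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
assignments <- function(x) x@assignments

#' @rdname annotation-accessors
#' @export
categories <- function(x) sort(unique(x@assignments$category))

#' @rdname annotation-accessors
#' @export
annotatedIds <- function(x, category = NULL) {
  d <- x@assignments
  if (!is.null(category)) d <- d[d$category %in% category, , drop = FALSE]
  unique(d$snp_id)
}

#' BayesFactorEstimate: an empirical annotation Bayes Factor
#'
#' The Bayes Factor for one annotation category, estimated as the proportion
#' of annotated SNPs in a hit set divided by the proportion in a panel
#' (background) set, with a delta-method standard error on the log scale.
#'
#' @slot category category name.
#' @slot k_hit,n_hit annotated / total counts in the hit set.
#' @slot k_panel,n_panel annotated / total counts in the panel set.
#' @slot bf the Bayes Factor (ratio of proportions).
#' @slot log_bf_se standard error of `log(bf)`; `NA` when `k_hit == 0`.
#'
#' @seealso [estimateBfAnnot()]
#' @exportClass BayesFactorEstimate
setClass("BayesFactorEstimate",
         representation(category = "character",
                        k_hit = "numeric", n_hit = "numeric",
                        k_panel = "numeric", n_panel = "numeric",
                        bf = "numeric", log_bf_se = "numeric"))

setValidity("BayesFactorEstimate", function(object) {
  if (object@k_hit > object@n_hit) return("k_hit exceeds n_hit")
  if (object@k_panel > object@n_panel) return("k_panel exceeds n_panel")
  if (object@bf < 0) return("bf must be >= 0")
  TRUE
})

setMethod("show", "BayesFactorEstimate", function(object) {
  cat(sprintf("BF_annot[%s] = %.3f  (hit %d/%d = %.4f, panel %d/%d = %.4f",
              object@category, object@bf,
              round(object@k_hit), round(object@n_hit),
              object@k_hit / object@n_hit,
              round(object@k_panel), round(object@n_panel),
              object@k_panel / object@n_panel))
  if (!is.na(object@log_bf_se))
    cat(sprintf(", se[log BF] = %.3f", object@log_bf_se))
  cat(")\n")
})

#' Accessors for BayesFactorEstimate
#'
#' `bfValue` returns the Bayes Factor, `logBfSE` the standard error of its
#' logarithm, `bfCounts` the four underlying counts.
#'
#' @param x a [BayesFactorEstimate-class]
#' @name bf-accessors
NULL

#' @rdname bf-accessors
#' @export
bfValue <- function(x) x@bf

#' @rdname bf-accessors
#' @export
logBfSE <- function(x) x@log_bf_se

#' @rdname bf-accessors
#' @export
bfCounts <- function(x) {
  c(k_hit = x@k_hit, n_hit = x@n_hit, k_panel = x@k_panel,
    n_panel = x@n_panel)
}
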