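#' Annotate SNPs by id membership
#'
#' Direct assignment of a category (e.g. `"nsSNP"`, a UCSC-derived id list)
#' to every SNP whose identifier appears in `idSet`.
#'
#' @param snps a [SnpSet-class].
#' @param idSet character vector of annotated SNP ids.
#' @param category annotation category name.
#' @return an [AnnotationSet-class] of direct assignments.
#' @export
annotateById <- function(snps, idSet, category) {
  hit <- snpIds(snps)[snpIds(snps) %in% idSet]
  AnnotationSet(snp_id = hit, category = category, provenance = "direct")
}

#' Annotate SNPs by interval containment
#'
#' Direct assignment of interval-borne categories (promoters, open
#' chromatin). A SNP at 1-based position `pos` is inside a BED interval
#' `[start0, end0)` iff `start0 < pos <= end0`; [readBedIntervals()] already
#' converts to 1-based closed ranges, so this is plain overlap. A SNP covered
#' by several intervals of the same category yields one assignment.
#'
#' @param snps a [SnpSet-class].
#' @param intervals a `GRanges` with metadata column `category` (from
#'   [readBedIntervals()], or several concatenated).
#' @return an [AnnotationSet-class] of direct assignments.
#' @export
annotateByPosition <- function(snps, intervals) {
  if (is.null(S4Vectors::mcols(intervals)$category))
    .stopUsage("intervals must carry a 'category' metadata column")
  if (length(intervals) == 0 || length(snps) == 0)
    return(AnnotationSet())
  hits <- GenomicRanges::findOverlaps(snpGRanges(snps),
                                      .normGRanges(intervals),
                                      ignore.strand = TRUE)
  AnnotationSet(
    snp_id = snpIds(snps)[S4Vectors::queryHits(hits)],
    category = S4Vectors::mcols(intervals)$category[S4Vectors::subjectHits(hits)],
    provenance = "direct")
}

#' Classify eQTLs as cis or trans
#'
#' An eQTL is *cis* when the SNP lies on the same chromosome as the
#' transcript it regulates and within `maxDist` base pairs (inclusive) of the
#' transcript's representative coordinate; otherwise *trans*.
#'
#' @param snpChrom,snpPos SNP chromosome and 1-based position (vectorised).
#' @param transcriptChrom,transcriptPos transcript chromosome and
#'   representative 1-based coordinate.
#' @param maxDist distance bound in bp (default 200 kb, inclusive).
#' @return character vector of `"cis"` / `"trans"`.
#' @export
classifyCisEqtl <- function(snpChrom, snpPos, transcriptChrom, transcriptPos,
                            maxDist = 200000) {
  cis <- .normChrom(snpChrom) == .normChrom(transcriptChrom) &
    abs(snpPos - transcriptPos) <= maxDist
  ifelse(cis, "cis", "trans")
}

#' Select eQTL SNPs by rank, cis status and open chromatin
#'
#' Filters an eQTL record table to the ids used as an annotation category:
#' keeps records whose expression-regression p-value rank is within
#' `maxRank`, optionally restricts to *cis* eQTLs (which requires SNP
#' positions from `snps`), and optionally intersects with open-chromatin
#' intervals.
#'
#' @param eqtls data.frame as returned by [readEqtlTable()].
#' @param maxRank keep records with `eqtl_rank <= maxRank` (e.g. 20000 or
#'   100000).
#' @param cisOnly restrict to cis eQTLs (within `maxDist` of the transcript).
#' @param openChromatin optional `GRanges` of open-chromatin intervals; when
#'   supplied, only SNPs inside them are kept.
#' @param snps a [SnpSet-class] supplying SNP coordinates; required when
#'   `cisOnly` or `openChromatin` is used. eQTL records whose SNP is absent
#'   from `snps` cannot be located and are dropped.
#' @param maxDist cis distance bound in bp (inclusive).
#' @return character vector of selected SNP ids.
#' @export
selectEqtls <- function(eqtls, maxRank, cisOnly = TRUE, openChromatin = NULL,
                        snps = NULL, maxDist = 200000) {
  if (maxRank < 1) .stopUsage("maxRank must be >= 1")
  d <- eqtls[eqtls$eqtl_rank <= maxRank, , drop = FALSE]
  if ((cisOnly || !is.null(openChromatin)) && is.null(snps))
    .stopUsage("snps is required for cis or open-chromatin filtering")
  if (cisOnly || !is.null(openChromatin)) {
    sd <- snpData(snps)
    idx <- match(d$snp_id, sd$snp_id)
    d <- d[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
    if (cisOnly) {
      keep <- classifyCisEqtl(sd$chrom[idx], sd$pos[idx],
                              d$transcript_chrom, d$transcript_pos,
                              maxDist = maxDist) == "cis"
      d <- d[keep, , drop = FALSE]
      idx <- idx[keep]
    }
    if (!is.null(openChromatin) && nrow(d) > 0) {
      gr <- GenomicRanges::GRanges(
        seqnames = .normChrom(sd$chrom[idx]),
        ranges = IRanges::IRanges(start = sd$pos[idx], width = 1L))
      inside <- GenomicRanges::countOverlaps(gr, .normGRanges(openChromatin),
                                             ignore.strand = TRUE) > 0
      d <- d[inside, , drop = FALSE]
    }
  }
  unique(d$snp_id)
}

#' Propagate annotations to LD proxies
#'
#' Adds an `ld_proxy` assignment for every SNP that has no direct assignment
#' in a category but is in linkage disequilibrium (`r2 >= r2Min`, pairs
#' unordered) with a directly annotated SNP. Propagation is single-hop:
#' proxy-acquired annotations never seed further propagation, so re-running
#' on the output adds nothing. Among several qualifying proxies the one with
#' the highest r2 (ties broken by id) is recorded as `proxy_source`.
#'
#' @param direct an [AnnotationSet-class]; only its `direct` rows seed
#'   propagation, but all its rows block re-assignment.
#' @param ld data.frame of LD pairs (columns `snp_a`, `snp_b`, `r2`), as from
#'   [readLdPairs()].
#' @param snps a [SnpSet-class]: the universe of SNPs eligible to receive
#'   proxy annotations.
#' @param r2Min inclusive r2 threshold (default 0.8).
#' @return an [AnnotationSet-class] containing `direct` plus the new
#'   `ld_proxy` assignments.
#' @export
propagateLdProxies <- function(direct, ld, snps, r2Min = 0.8) {
  if (r2Min <= 0 || r2Min > 1) .stopUsage("r2Min must lie in (0, 1]")
  da <- assignments(direct)
  edges <- ld[ld$r2 >= r2Min, , drop = FALSE]
  if (nrow(edges) == 0 || nrow(da) == 0) return(direct)
  # unordered pairs: keep both directions (from = candidate, to = seed)
  edges <- data.frame(
    from = c(edges$snp_a, edges$snp_b),
    to = c(edges$snp_b, edges$snp_a),
    r2 = c(edges$r2, edges$r2),
    stringsAsFactors = FALSE)
  edges <- edges[edges$from %in% snpIds(snps), , drop = FALSE]

  seeds <- da[da$provenance == "direct", , drop = FALSE]
  new_rows <- lapply(unique(seeds$category), function(cat) {
    seed_ids <- seeds$snp_id[seeds$category == cat]
    already <- da$snp_id[da$category == cat]
    e <- edges[edges$to %in% seed_ids & !(edges$from %in% already), ,
               drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    e <- e[order(e$from, -e$r2, e$to), , drop = FALSE]
    e <- e[!duplicated(e$from), , drop = FALSE]
    data.frame(snp_id = e$from, category = cat, provenance = "ld_proxy",
               proxy_source = e$to, stringsAsFactors = FALSE)
  })
  new_rows <- do.call(rbind, new_rows)
  if (is.null(new_rows)) return(direct)
  new("AnnotationSet",
      assignments = .dedupAssignments(rbind(da, new_rows)))
}

#' SNPs carrying exactly one annotation category
#'
#' For independence checks between categories: returns, per category, the
#' SNPs assigned (by any provenance) to that category and to no other. A SNP
#' with assignments in two or more categories is excluded from all of them.
#'
#' @param annot an [AnnotationSet-class].
#' @return named list of character vectors, one per category.
#' @export
uniqueAnnotationSubset <- function(annot) {
  d <- assignments(annot)
  if (nrow(d) == 0) return(setNames(list(), character(0)))
  ncat <- tapply(d$category, d$snp_id, function(x) length(unique(x)))
  solo <- names(ncat)[ncat == 1]
  out <- lapply(categories(annot), function(cat) {
    ids <- unique(d$snp_id[d$category == cat])
    ids[ids %in% solo]
  })
  setNames(out, categories(annot))
}
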