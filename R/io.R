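#' Read a PLINK-style association table
#'
#' Reads a whitespace-delimited association table with a header row, as
#' written by PLINK (`.assoc`, `.assoc.logistic` and similar layouts).
#' Columns are matched by name, case-insensitively: `SNP`, `CHR` and `BP` are
#' mandatory, `P` is mandatory as a column but individual rows whose p-value
#' does not parse (e.g. `NA`) are dropped with a warning naming the row
#' numbers. Optional columns: `OR` (converted to a log-odds `beta_hat` by
#' natural log), `BETA` (used as-is; takes precedence over `OR` when both are
#' present), `SE` and `MAF`. Plain or gzip input is accepted.
#'
#' @param file path (optionally `.gz`) or a connection.
#' @param panels optional character vector of panel names attached to every
#'   SNP read.
#' @return a [SnpSet-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("SNP CHR BP P OR SE", "rs1 1 1000 0.5 1.0 0.1"), tf)
#' readAssocTable(tf)
#' @export
readAssocTable <- function(file, panels = NULL) {
  con <- .openInput(file)
  if (inherits(con, "connection")) on.exit(close(con))
  d <- read.table(con, header = TRUE, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE,
                  comment.char = "#")
  cols <- setNames(seq_along(names(d)), toupper(names(d)))
  for (m in c("SNP", "CHR", "BP", "P")) {
    if (!m %in% names(cols))
      .stopFormat("association table is missing mandatory column '", m, "'")
  }
  pick <- function(nm) if (nm %in% names(cols)) d[[cols[[nm]]]] else NULL

  snp_id <- pick("SNP")
  if (anyDuplicated(snp_id))
    .stopFormat("duplicate snp_id in association table: ",
                paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))

  p <- suppressWarnings(as.numeric(pick("P")))
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with unparseable or out-of-range P: row %s",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
  }
  keep <- !bad

  beta <- rep(NA_real_, length(snp_id))
  if (!is.null(pick("BETA"))) {
    beta <- suppressWarnings(as.numeric(pick("BETA")))
  } else if (!is.null(pick("OR"))) {
    or <- suppressWarnings(as.numeric(pick("OR")))
    beta <- ifelse(!is.na(or) & or > 0, log(or), NA_real_)
  }
  se <- if (!is.null(pick("SE"))) suppressWarnings(as.numeric(pick("SE"))) else NA_real_
  maf <- if (!is.null(pick("MAF"))) suppressWarnings(as.numeric(pick("MAF"))) else NA_real_

  SnpSet(snp_id = snp_id[keep],
         chrom = pick("CHR")[keep],
         pos = suppressWarnings(as.numeric(pick("BP")))[keep],
         maf = rep_len(maf, length(snp_id))[keep],
         p_assoc = p[keep],
         beta_hat = rep_len(beta, length(snp_id))[keep],
         se = rep_len(se, length(snp_id))[keep],
         panels = panels)
}

#' Read BED intervals into a GRanges
#'
#' Reads a 3+ column BED file (0-based half-open coordinates) and returns a
#' 1-based closed [GenomicRanges::GRanges] — BED `start end` becomes
#' `[start+1, end]` — tagged with a caller-supplied annotation category.
#' Zero-length or inverted intervals (`start >= end`) are a format error
#' reporting the offending line number. Plain or gzip input is accepted.
#'
#' @param file path (optionally `.gz`) or a connection.
#' @param category annotation category name attached to every interval
#'   (metadata column `category`).
#' @return a `GRanges` with metadata column `category`.
#' @examples
#' tf <- tempfile()
#' writeLines("chr1\t99\t200", tf)
#' readBedIntervals(tf, category = "promoter")
#' @export
readBedIntervals <- function(file, category) {
  if (missing(category) || !nzchar(category))
    .stopUsage("readBedIntervals() requires a category label")
  con <- .openInput(file)
  if (inherits(con, "connection")) on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$category <- character(0)
    return(gr)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    .stopFormat("BED line ", which(nf < 3)[1], " has fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0))
    .stopFormat("BED line ", which(is.na(start0) | is.na(end0))[1],
                " has non-numeric coordinates")
  bad <- start0 >= end0 | start0 < 0
  if (any(bad))
    .stopFormat("BED line ", which(bad)[1], " has start >= end (or start < 0): ",
                lines[which(bad)[1]])
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0))
  S4Vectors::mcols(gr)$category <- category
  gr
}

## Rebuild a GRanges with "chr"-stripped seqnames so tracks labelled "chr1"
## and tables labelled "1" overlap correctly.
.normGRanges <- function(gr) {
  out <- GenomicRanges::GRanges(
    seqnames = .normChrom(GenomicRanges::seqnames(gr)),
    ranges = IRanges::ranges(gr))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

#' Write intervals back to BED
#'
#' Serialises a 1-based `GRanges` (as returned by [readBedIntervals()]) to
#' 3-column BED, restoring the 0-based half-open convention.
#'
#' @param gr a `GRanges`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeBedIntervals <- function(gr, file) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1,
                  end = GenomicRanges::end(gr))
  write.table(format(d, scientific = FALSE, trim = TRUE), file,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a pairwise LD table
#'
#' Reads a whitespace-delimited table of SNP pairs with squared correlations
#' (SNAP-style: two SNP id columns and an r2 column, matched by name
#' case-insensitively among `SNP1`/`SNP_A`/`SNP`, `SNP2`/`SNP_B`/`PROXY` and
#' `R2`/`RSQUARED`; a headerless 3-column layout is also accepted). Pairs are
#' unordered; self-pairs are dropped; r2 outside `[0, 1]` or non-numeric is a
#' format error.
#'
#' @param file path (optionally `.gz`) or a connection.
#' @return a data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
readLdPairs <- function(file) {
  con <- .openInput(file)
  if (inherits(con, "connection")) on.exit(close(con))
  first <- readLines(con, n = 1)
  if (length(first) == 0)
    return(data.frame(snp_a = character(0), snp_b = character(0),
                      r2 = numeric(0)))
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(toks[length(toks)])))
  rest <- readLines(con)
  lines <- c(if (!has_header) first, rest)
  lines <- lines[nzchar(trimws(lines))]
  if (has_header) {
    up <- toupper(toks)
    ia <- match(TRUE, up %in% c("SNP1", "SNP_A", "SNP"))
    ib <- match(TRUE, up %in% c("SNP2", "SNP_B", "PROXY"))
    ir <- match(TRUE, up %in% c("R2", "RSQUARED"))
    if (anyNA(c(ia, ib, ir)))
      .stopFormat("LD table header must name two SNP columns and an r2 column")
  } else {
    ia <- 1L; ib <- 2L; ir <- 3L
  }
  if (length(lines) == 0)
    return(data.frame(snp_a = character(0), snp_b = character(0),
                      r2 = numeric(0)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < max(ia, ib, ir)))
    .stopFormat("LD table line ", which(lengths(fields) < max(ia, ib, ir))[1],
                " has too few columns")
  snp_a <- vapply(fields, `[[`, "", ia)
  snp_b <- vapply(fields, `[[`, "", ib)
  r2 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", ir)))
  if (anyNA(r2))
    .stopFormat("non-numeric r2 at LD table line ", which(is.na(r2))[1])
  if (any(r2 < 0 | r2 > 1))
    .stopFormat("r2 outside [0, 1] at LD table line ",
                which(r2 < 0 | r2 > 1)[1])
  d <- data.frame(snp_a = snp_a, snp_b = snp_b, r2 = r2,
                  stringsAsFactors = FALSE)
  d <- d[d$snp_a != d$snp_b, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read a plain SNP-id list
#'
#' One id per line; blank lines and `#` comments ignored.
#'
#' @param file path (optionally `.gz`) or a connection.
#' @return character vector of unique ids.
#' @export
readSnpList <- function(file) {
  con <- .openInput(file)
  if (inherits(con, "connection")) on.exit(close(con))
  x <- trimws(readLines(con))
  unique(x[nzchar(x) & !grepl("^#", x)])
}

#' Read an eQTL record table
#'
#' Whitespace-delimited with header; columns (case-insensitive): `SNP`,
#' `TRANSCRIPT_CHR`, `TRANSCRIPT_POS` (a representative 1-based coordinate of
#' the regulated transcript) and `RANK` (integer rank of the expression
#' regression p-value, 1 = most significant).
#'
#' @param file path (optionally `.gz`) or a connection.
#' @return data.frame with columns `snp_id`, `transcript_chrom`,
#'   `transcript_pos`, `eqtl_rank`.
#' @export
readEqtlTable <- function(file) {
  con <- .openInput(file)
  if (inherits(con, "connection")) on.exit(close(con))
  d <- read.table(con, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  cols <- setNames(seq_along(names(d)), toupper(names(d)))
  for (m in c("SNP", "TRANSCRIPT_CHR", "TRANSCRIPT_POS", "RANK"))
    if (!m %in% names(cols))
      .stopFormat("eQTL table is missing mandatory column '", m, "'")
  out <- data.frame(snp_id = as.character(d[[cols[["SNP"]]]]),
                    transcript_chrom = as.character(d[[cols[["TRANSCRIPT_CHR"]]]]),
                    transcript_pos = as.numeric(d[[cols[["TRANSCRIPT_POS"]]]]),
                    eqtl_rank = as.integer(d[[cols[["RANK"]]]]),
                    stringsAsFactors = FALSE)
  if (any(out$eqtl_rank < 1)) .stopFormat("eQTL rank must be >= 1")
  out
}

#' Remove SNPs in the extended MHC region
#'
#' Drops SNPs inside chr6:25,809,985-33,486,934 (bounds inclusive), the
#' gene-dense, long-range-LD major histocompatibility complex region whose
#' hits are unrepresentative of the rest of the genome. Chromosome labels
#' `"6"` and `"chr6"` are both recognised. Idempotent; input order preserved.
#'
#' @param snps a [SnpSet-class].
#' @param start,end region bounds (1-based, inclusive).
#' @return the filtered `SnpSet`.
#' @export
filterMhc <- function(snps, start = 25809985, end = 33486934) {
  d <- snpData(snps)
  inside <- .normChrom(d$chrom) == "6" & d$pos >= start & d$pos <= end
  snps[!inside]
}

#' Restrict hit SNPs to the genotyping panel(s)
#'
#' GWAS hit lists often include SNPs genotyped only for replication, which
#' are preferentially selected on annotation and would bias enrichment
#' estimates; this keeps only hits present on the original panels. With
#' `mode = "union"` a SNP found on several panels is counted once; with
#' `mode = "summation"` it is returned once per panel carrying it (the two
#' endpoints of how overlapping panels can be combined).
#'
#' @param hits a [SnpSet-class] of hit SNPs.
#' @param panels a character vector of panel SNP ids (one panel), or a named
#'   list of such vectors (several panels).
#' @param mode `"union"` or `"summation"`.
#' @return for `"union"`, a deduplicated `SnpSet`; for `"summation"`, a
#'   data.frame with columns `snp_id` and `panel`, one row per
#'   (SNP, panel) membership.
#' @export
restrictToPanel <- function(hits, panels, mode = c("union", "summation")) {
  mode <- match.arg(mode)
  if (is.character(panels)) panels <- list(panel = panels)
  if (length(panels) == 0 || all(lengths(panels) == 0))
    .stopUsage("panels must contain at least one SNP id")
  if (is.null(names(panels)))
    names(panels) <- paste0("panel", seq_along(panels))
  ids <- snpIds(hits)
  if (mode == "union") {
    keep <- ids %in% unique(unlist(panels))
    return(hits[keep])
  }
  rows <- lapply(names(panels), function(pn) {
    hit <- ids[ids %in% panels[[pn]]]
    if (length(hit) == 0) return(NULL)
    data.frame(snp_id = hit, panel = pn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp_id = character(0), panel = character(0))
  rownames(out) <- NULL
  out
}

#' Write a SnpSet as a PLINK-style association table
#'
#' Columns `SNP CHR BP MAF P BETA SE`, whitespace-delimited with header —
#' readable back with [readAssocTable()].
#'
#' @param snps a [SnpSet-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeAssocTable <- function(snps, file) {
  d <- snpData(snps)
  out <- data.frame(SNP = d$snp_id, CHR = d$chrom, BP = d$pos,
                    MAF = d$maf, P = d$p_assoc, BETA = d$beta_hat, SE = d$se)
  write.table(out, file, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an LD-pair table
#'
#' @param ld data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeLdPairs <- function(ld, file) {
  out <- data.frame(SNP1 = ld$snp_a, SNP2 = ld$snp_b, R2 = ld$r2)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a plain SNP-id list
#'
#' @param ids character vector of SNP ids.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSnpList <- function(ids, file) {
  writeLines(ids, file)
  invisible(file)
}
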