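# Small in-code fixtures shared across test files.

# Six SNPs on two chromosomes, two of them inside the MHC region.
tinySnps <- function() {
  SnpSet(snp_id = paste0("rs", 1:6),
         chrom = c("1", "1", "6", "6", "6", "2"),
         pos = c(1000, 5000, 25809984, 25809985, 33486934, 3e7),
         maf = c(0.05, 0.2, 0.1, 0.3, NA, 0.45))
}

# Write lines to a tempfile and return its path.
tmpLines <- function(lines, ext = "") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Brute-force containment oracle: SNP (1-based pos) inside a BED-style
# 0-based half-open interval iff start0 < pos <= end0.
bruteOverlap <- function(snpChrom, snpPos, ivChrom, ivStart0, ivEnd0) {
  out <- logical(length(snpPos))
  for (i in seq_along(snpPos)) {
    out[i] <- any(ivChrom == snpChrom[i] &
                    ivStart0 < snpPos[i] & snpPos[i] <= ivEnd0)
  }
  out
}
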