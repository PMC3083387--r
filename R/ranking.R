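#' Rank scores, largest first
#'
#' Rank 1 is the best (largest) score; ties receive the average of the ranks
#' they span.
#'
#' @param values positive, finite scores (names preserved).
#' @return numeric vector of ranks.
#' @export
rankValues <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    .stopUsage("values must be positive and finite")
  r <- rank(-values, ties.method = "average")
  names(r) <- names(values)
  r
}

#' Rank change of target SNPs under annotation weighting
#'
#' Ranks all SNPs by `BF_assoc` alone and by `BF_assoc * BF_annot`, then
#' summarises how a set of target SNPs moved: per-target change is
#' `rank_before - rank_after` (positive = moved up, i.e. improved), with the
#' mean change and the count of strict improvements.
#'
#' @param bfAssoc named numeric vector of association Bayes Factors for all
#'   SNPs.
#' @param bfAnnot named numeric vector of annotation Bayes Factors, same
#'   SNPs.
#' @param targets character vector of target SNP ids (subset of the names of
#'   `bfAssoc`).
#' @return list with `per_target` (data.frame of per-SNP ranks and change),
#'   `mean_change` and `n_moved_up`.
#' @export
rankChange <- function(bfAssoc, bfAnnot, targets) {
  if (length(targets) == 0) .stopUsage("targets must be nonempty")
  if (is.null(names(bfAssoc)) ||
      !identical(sort(names(bfAssoc)), sort(names(bfAnnot))))
    .stopUsage("bfAssoc and bfAnnot must be named over the same SNPs")
  if (!all(targets %in% names(bfAssoc)))
    .stopUsage("targets missing from scored SNPs: ",
               paste(setdiff(targets, names(bfAssoc)), collapse = ", "))
  bfAnnot <- bfAnnot[names(bfAssoc)]
  before <- rankValues(bfAssoc)
  after <- rankValues(bfAssoc * bfAnnot)
  chg <- (before - after)[targets]
  list(per_target = data.frame(snp_id = targets,
                               rank_before = before[targets],
                               rank_after = after[targets],
                               change = chg,
                               row.names = NULL,
                               stringsAsFactors = FALSE),
       mean_change = mean(chg),
       n_moved_up = sum(chg > 0))
}

#' Random-set baseline for rank change
#'
#' The null expectation for [rankChange()]: repeatedly samples sets of SNPs
#' (without replacement within a set) and records each set's mean rank change
#' and moved-up count. By default the target SNPs are excluded from the
#' sampling frame so the null is uncontaminated; set `exclude = NULL` to
#' sample from all SNPs.
#'
#' @param bfAssoc,bfAnnot named numeric vectors over the same SNPs.
#' @param setSize SNPs per random set.
#' @param nSets number of random sets (default 100).
#' @param seed integer seed; recorded in the output.
#' @param exclude SNP ids excluded from sampling (typically the targets).
#' @return list: `mean_changes` and `moved_up` (length-`nSets` vectors),
#'   `set_size`, `n_sets`, `seed`.
#' @export
randomSetBaseline <- function(bfAssoc, bfAnnot, setSize, nSets = 100,
                              seed = 1, exclude = NULL) {
  if (nSets < 1) .stopUsage("nSets must be >= 1")
  bfAnnot <- bfAnnot[names(bfAssoc)]
  pool <- setdiff(names(bfAssoc), exclude)
  if (setSize > length(pool))
    .stopUsage("setSize exceeds the number of available SNPs")
  before <- rankValues(bfAssoc)
  after <- rankValues(bfAssoc * bfAnnot)
  chg <- before - after
  res <- withr::with_seed(seed, {
    vapply(seq_len(nSets), function(i) {
      s <- sample(pool, setSize)
      c(mean(chg[s]), sum(chg[s] > 0))
    }, numeric(2))
  })
  list(mean_changes = res[1, ], moved_up = res[2, ],
       set_size = setSize, n_sets = nSets, seed = seed)
}

#' Full rank-change report with baseline
#'
#' Runs [rankChange()] for the targets and [randomSetBaseline()] for
#' equally sized random sets, and summarises both.
#'
#' @inheritParams randomSetBaseline
#' @param targets character vector of target SNP ids.
#' @param excludeTargets exclude targets from baseline sampling (default
#'   `TRUE`).
#' @return list: `targets`, `mean_rank_change`, `n_moved_up`,
#'   `baseline_mean_changes`, `baseline_moved_up`, `baseline_mean_moved_up`,
#'   `baseline_q95` (95th percentile of baseline mean changes), `set_size`,
#'   `n_sets`, `seed`.
#' @export
rankChangeReport <- function(bfAssoc, bfAnnot, targets, nSets = 100,
                             seed = 1, excludeTargets = TRUE) {
  rc <- rankChange(bfAssoc, bfAnnot, targets)
  bl <- randomSetBaseline(bfAssoc, bfAnnot, setSize = length(targets),
                          nSets = nSets, seed = seed,
                          exclude = if (excludeTargets) targets else NULL)
  list(targets = targets,
       per_target = rc$per_target,
       mean_rank_change = rc$mean_change,
       n_moved_up = rc$n_moved_up,
       baseline_mean_changes = bl$mean_changes,
       baseline_moved_up = bl$moved_up,
       baseline_mean_moved_up = mean(bl$moved_up),
       baseline_q95 = unname(stats::quantile(bl$mean_changes, 0.95)),
       set_size = length(targets), n_sets = nSets, seed = seed)
}
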