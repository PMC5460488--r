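#' Rank-biserial correlation between gene scores and set membership
#'
#' The effect-size measure behind every set-level analysis in the pipeline:
#' with midranks `R` over the scores of the `N` universe genes,
#' `r_rb = 2 (mean R among members - mean R among non-members) / N`, which
#' equals `2U/(n1 n0) - 1` where the Mann-Whitney `U` counts member-over-
#' non-member wins with ties worth 1/2.
#'
#' @param scores numeric scores over the universe (higher = stronger signal).
#' @param membership logical (or 0/1) indicator, same length as `scores`.
#' @return `r_rb` in `[-1, 1]`.
#' @export
rank_biserial <- function(scores, membership) {
  membership <- as.logical(membership)
  N <- length(scores)
  if (length(membership) != N)
    stop("'scores' and 'membership' lengths differ", call. = FALSE)
  if (N < 2) stop("universe must contain at least 2 genes", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n1 <- sum(membership)
  if (n1 == 0 || n1 == N)
    stop("rank-biserial undefined: one membership class is empty",
         call. = FALSE)
  R <- rank(scores)
  2 * (mean(R[membership]) - mean(R[!membership])) / N
}

#' Bootstrap standard error of the rank-biserial correlation
#'
#' Resamples the universe genes (score, membership pairs) with replacement
#' `B` times and reports the standard deviation of the replicate `r_rb`.
#' Replicates in which one membership class vanishes are redrawn, so the SE
#' is over exactly `B` valid replicates.
#'
#' @inheritParams rank_biserial
#' @param B number of bootstrap replicates (default 10000).
#' @param seed integer seed for the resampling stream.
#' @param return_replicates return the replicate values as an attribute
#'   (for diagnostics).
#' @return the bootstrap standard error; attributes `redraws` (count of
#'   degenerate replicates redrawn) and, optionally, `replicates`.
#' @export
bootstrap_se <- function(scores, membership, B = 10000, seed = 1,
                         return_replicates = FALSE) {
  membership <- as.logical(membership)
  if (B < 2) stop("'B' must be at least 2", call. = FALSE)
  rank_biserial(scores, membership)  # validates the input
  res <- bootstrap_rrb_cpp(as.numeric(scores), as.integer(membership),
                           as.integer(B), as.numeric(seed),
                           return_replicates)
  out <- res$se
  attr(out, "redraws") <- res$redraws
  if (return_replicates) attr(out, "replicates") <- res$replicates
  out
}

#' Enrichment of every sufficiently large set in a collection
#'
#' Computes `r_rb` (and, optionally, its bootstrap SE) for every set with at
#' least `min_genes` members among the scored genes. The universe is the set
#' of genes present in the score table; sets below the threshold are omitted
#' and counted in the `n_skipped` attribute.
#'
#' @param score_table a [gene_score_table()].
#' @param collection a [gene_set_collection()].
#' @param min_genes minimum number of measured member genes (default 50).
#' @param B bootstrap replicates for the SE; `B = 0` skips the bootstrap and
#'   reports `NA` SEs.
#' @param seed master seed; each set uses a sub-seed derived from it and the
#'   set id, so per-set results do not depend on iteration order.
#' @return a data frame (`set`, `collection`, `n_genes`, `r_rb`, `se`,
#'   `n_universe`), sorted by decreasing `r_rb`, with attribute `n_skipped`.
#' @export
enrich_collection <- function(score_table, collection, min_genes = 50,
                              B = 10000, seed = 1) {
  stopifnot(inherits(score_table, "gene_score_table"),
            inherits(collection, "gene_set_collection"))
  universe <- names(score_table$scores)
  if (length(universe) == 0) stop("empty score universe", call. = FALSE)
  scores <- as.numeric(score_table$scores)
  rows <- list()
  n_skipped <- 0L
  for (nm in names(collection$sets)) {
    memb <- universe %in% collection$sets[[nm]]$genes
    n <- sum(memb)
    if (n < min_genes || n == length(universe)) {
      n_skipped <- n_skipped + 1L
      next
    }
    r <- rank_biserial(scores, memb)
    se <- if (B > 0)
      as.numeric(bootstrap_se(scores, memb, B = B,
                              seed = derive_seed(seed, nm)))
    else NA_real_
    rows[[nm]] <- data.frame(set = nm,
                             collection = collection$collection_id,
                             n_genes = n, r_rb = r, se = se,
                             n_universe = length(universe),
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(set = character(0), collection = character(0),
               n_genes = integer(0), r_rb = numeric(0), se = numeric(0),
               n_universe = integer(0))
  out <- out[order(-out$r_rb), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
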