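#' Gene-level correlation between two score tables
#'
#' Spearman correlation, over the shared genes, between per-gene
#' differential-expression scores and one study's adaptation scores, with a
#' one-tailed permutation p-value: the fraction of `B` permutations of the
#' adaptation scores whose correlation is at least the observed one,
#' reported as `"<1/B"` when no replicate reaches it.
#'
#' @param de_scores,adapt_scores [gene_score_table()] objects.
#' @param B number of permutations (default 10000).
#' @param seed integer seed.
#' @return `list(n_genes =, r_r =, p =, p_num =, B =)`.
#' @export
genic_correlation <- function(de_scores, adapt_scores, B = 10000, seed = 1) {
  stopifnot(inherits(de_scores, "gene_score_table"),
            inherits(adapt_scores, "gene_score_table"))
  genes <- intersect(names(de_scores$scores), names(adapt_scores$scores))
  if (length(genes) < 10)
    stop("need >= 10 genes shared between the score tables", call. = FALSE)
  x <- de_scores$scores[genes]
  y <- adapt_scores$scores[genes]
  r_obs <- spearman(x, y)
  if (is.na(r_obs)) stop("constant score vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rx_c <- rx - mean(rx)
  set.seed(derive_seed(seed, "genic"))
  hits <- 0L
  denom_x <- sqrt(sum(rx_c^2))
  for (b in seq_len(B)) {
    ryp <- ry[sample.int(length(ry))]
    r <- sum(rx_c * (ryp - mean(ryp))) / (denom_x * sqrt(sum((ryp - mean(ryp))^2)))
    if (r >= r_obs - 1e-12) hits <- hits + 1L
  }
  p_num <- if (hits == 0) 1 / B else hits / B
  p <- if (hits == 0) sprintf("<%g", 1 / B) else format(hits / B)
  list(n_genes = length(genes), r_r = r_obs, p = p, p_num = p_num, B = B)
}

#' Spearman correlation between two per-set enrichment profiles
#'
#' The "functional correlation" statistic: the midrank Spearman correlation,
#' over the gene sets of one collection, between the sets' enrichment with
#' differential expression and their (meta-combined) enrichment with
#' adaptation.
#'
#' @param de_enrichment named numeric: per-set `r_rb` for differential
#'   expression.
#' @param adapt_meta named numeric: per-set combined `WM(r_rb)` for
#'   adaptation; matched to `de_enrichment` by name.
#' @return the Spearman correlation (`NA` if either profile is constant).
#' @export
spearman_over_sets <- function(de_enrichment, adapt_meta) {
  sets <- intersect(names(de_enrichment), names(adapt_meta))
  if (length(sets) < 2)
    stop("need >= 2 matched sets", call. = FALSE)
  spearman(de_enrichment[sets], adapt_meta[sets])
}

# permuted rank matrix: each column a random permutation of `ranks`
permuted_rank_matrix <- function(ranks, B) {
  n <- length(ranks)
  vapply(seq_len(B), function(b) ranks[sample.int(n)], numeric(n))
}

# per-set r_rb for every permutation column: M is the sets x genes
# membership indicator over the universe, P the genes x B permuted midranks
rrb_from_rank_matrix <- function(M, P, n1, N) {
  sm <- M %*% P                              # sets x B member rank sums
  total <- N * (N + 1) / 2
  n0 <- N - n1
  2 * (sm / n1 - (total - sm) / n0) / N
}

# column-wise Spearman correlation between two S x B matrices
colwise_spearman <- function(A, B_) {
  ra <- apply(A, 2, rank)
  rb <- apply(B_, 2, rank)
  ra <- sweep(ra, 2, colMeans(ra))
  rb <- sweep(rb, 2, colMeans(rb))
  num <- colSums(ra * rb)
  den <- sqrt(colSums(ra^2) * colSums(rb^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Overlap-aware permutation test of per-collection functional correlations
#'
#' Runs the observed pipeline (per-study adaptation enrichment with
#' bootstrap SEs, fixed-effects meta-combination with heterogeneity and
#' size filters, differential-expression enrichment, Spearman correlation
#' over retained sets), then builds the null by permuting gene-level scores:
#' in each replicate the DE scores are permuted among the DE universe genes
#' and each study's adaptation scores are independently permuted among the
#' genes that study covers; every per-set `r_rb` is recomputed against the
#' fixed set memberships, the meta-combined value is recomputed with the
#' observed (frozen) weights and retained-set lists, and the replicate
#' correlation is compared with the observed one. Because set overlap is
#' preserved in every replicate, correlated set statistics do not inflate
#' significance. The one-tailed p is the fraction of replicates with
#' `r_r >= observed`, reported `"<1/B"` when none.
#'
#' The naive alternative that permutes set-level values among sets (which
#' ignores overlap and tends to inflate significance) is available as a
#' diagnostic via `permute = "sets"`.
#'
#' @param de_scores [gene_score_table()] of per-gene DE scores.
#' @param adapt_tables list of [gene_score_table()], one per study.
#' @param collections list of [gene_set_collection()].
#' @param min_genes minimum measured genes per set (default 50).
#' @param B permutation replicates (default 10000).
#' @param seed integer master seed.
#' @param boot_B bootstrap replicates for per-study SEs (default 1000).
#' @param min_studies,alpha_q,min_mean_genes meta-analytic retention
#'   filters, see [combine_studies()].
#' @param permute `"genes"` (overlap-aware, default) or `"sets"` (naive
#'   diagnostic).
#' @param joint permute DE and adaptation scores with the same gene
#'   relabelling instead of independently. Independent permutation (the
#'   default) is the stricter null for a correlation between the two sides;
#'   the joint variant requires every score table to cover exactly the same
#'   genes.
#' @param block permutations processed per matrix block.
#' @return a `funcorr_result` data frame: `collection`, `n_sets`, `r_r`,
#'   `p`, `p_num`, `q`, `B`; attribute `details` holds the per-collection
#'   observed tables (DE enrichment, per-study enrichment, meta table,
#'   retained set list).
#' @export
overlap_aware_permutation_test <- function(de_scores, adapt_tables,
                                           collections, min_genes = 50,
                                           B = 10000, seed = 1,
                                           boot_B = 1000, min_studies = 2,
                                           alpha_q = 0.05,
                                           min_mean_genes = 50,
                                           permute = c("genes", "sets"),
                                           joint = FALSE, block = 1000) {
  permute <- match.arg(permute)
  stopifnot(inherits(de_scores, "gene_score_table"), is.list(adapt_tables),
            is.list(collections))
  if (B < 100) warning("B < 100 gives a very coarse permutation p-value")
  if (joint && !all(vapply(adapt_tables, function(tab)
    setequal(names(tab$scores), names(de_scores$scores)), logical(1))))
    stop("joint permutation requires every table to cover the same genes",
         call. = FALSE)

  de_universe <- names(de_scores$scores)
  de_ranks <- rank(de_scores$scores)
  details <- list()
  obs <- list()

  for (coll in collections) {
    cid <- coll$collection_id
    de_enr <- enrich_collection(de_scores, coll, min_genes = min_genes, B = 0)
    adapt_enr <- lapply(adapt_tables, function(tab)
      enrich_collection(tab, coll, min_genes = min_genes, B = boot_B,
                        seed = derive_seed(seed, paste0("boot_", tab$study_id))))
    meta <- combine_studies(adapt_enr, min_studies = min_studies,
                            alpha_q = alpha_q,
                            min_mean_genes = min_mean_genes)
    sets_use <- intersect(meta$set[meta$retained], de_enr$set)
    details[[cid]] <- list(de_enrichment = de_enr, adapt_enrichment = adapt_enr,
                           meta = meta, sets = sets_use)
    if (length(sets_use) < 2) {
      message("collection ", cid, ": fewer than 2 retained sets, skipped")
      obs[[cid]] <- NULL
      next
    }
    de_vec <- setNames(de_enr$r_rb, de_enr$set)[sets_use]
    wm_vec <- setNames(meta$wm, meta$set)[sets_use]
    obs[[cid]] <- list(r_obs = spearman_over_sets(de_vec, wm_vec),
                       de_vec = de_vec, wm_vec = wm_vec)
  }

  tested <- names(obs)[!vapply(obs, is.null, logical(1))]
  rows <- list()
  set.seed(derive_seed(seed, paste0("perm_", permute)))

  if (permute == "genes") {
    # precompute per-collection membership structures over each universe
    prep <- list()
    for (cid in tested) {
      coll <- collections[[which(vapply(collections, `[[`, "", "collection_id")
                                 == cid)]]
      sets_use <- details[[cid]]$sets
      memb_de <- t(vapply(sets_use, function(nm)
        as.numeric(de_universe %in% coll$sets[[nm]]$genes),
        numeric(length(de_universe))))
      w_by_set <- attr(details[[cid]]$meta, "weights")
      per_study <- lapply(seq_along(adapt_tables), function(i) {
        uni <- names(adapt_tables[[i]]$scores)
        enr <- details[[cid]]$adapt_enrichment[[i]]
        in_study <- sets_use[sets_use %in% enr$set]
        if (length(in_study) == 0) return(NULL)
        M <- t(vapply(in_study, function(nm)
          as.numeric(uni %in% coll$sets[[nm]]$genes), numeric(length(uni))))
        w <- vapply(in_study, function(nm) {
          wv <- w_by_set[[nm]]
          unname(wv[paste0("study", i)])
        }, numeric(1))
        list(M = M, n1 = rowSums(M), N = length(uni), sets = in_study,
             ranks = rank(adapt_tables[[i]]$scores), w = w)
      })
      prep[[cid]] <- list(M_de = memb_de, n1_de = rowSums(memb_de),
                          N_de = length(de_universe),
                          per_study = per_study, sets = sets_use)
    }

    hits <- setNames(rep(0, length(tested)), tested)
    valid <- setNames(rep(0, length(tested)), tested)
    done <- 0
    while (done < B) {
      b <- min(block, B - done)
      if (joint) {
        N <- length(de_ranks)
        idx <- vapply(seq_len(b), function(i) sample.int(N), integer(N))
        P_de <- matrix(de_ranks[idx], nrow = N)
        perm_genes <- matrix(de_universe[idx], nrow = N)
        P_st <- lapply(adapt_tables, function(tab) {
          r_by_gene <- rank(tab$scores)
          pos <- match(names(tab$scores), de_universe)
          matrix(r_by_gene[perm_genes[pos, , drop = FALSE]],
                 nrow = length(pos))
        })
      } else {
        P_de <- permuted_rank_matrix(de_ranks, b)
        P_st <- lapply(adapt_tables, function(tab)
          permuted_rank_matrix(rank(tab$scores), b))
      }
      for (cid in tested) {
        pp <- prep[[cid]]
        de_rep <- rrb_from_rank_matrix(pp$M_de, P_de, pp$n1_de, pp$N_de)
        wm_rep <- matrix(0, length(pp$sets), b,
                         dimnames = list(pp$sets, NULL))
        for (i in seq_along(pp$per_study)) {
          ps <- pp$per_study[[i]]
          if (is.null(ps)) next
          r_i <- rrb_from_rank_matrix(ps$M, P_st[[i]], ps$n1, ps$N)
          wm_rep[ps$sets, ] <- wm_rep[ps$sets, , drop = FALSE] +
            ps$w * r_i
        }
        rr <- colwise_spearman(de_rep, wm_rep)
        ok <- !is.na(rr)
        hits[cid] <- hits[cid] + sum(rr[ok] >= obs[[cid]]$r_obs - 1e-12)
        valid[cid] <- valid[cid] + sum(ok)
      }
      done <- done + b
    }
    for (cid in tested) {
      h <- hits[cid]
      p_num <- if (h == 0) 1 / B else h / B
      rows[[cid]] <- data.frame(
        collection = cid, n_sets = length(prep[[cid]]$sets),
        r_r = obs[[cid]]$r_obs,
        p = if (h == 0) sprintf("<%g", 1 / B) else format(h / B),
        p_num = p_num, B = B, stringsAsFactors = FALSE)
    }
  } else {
    for (cid in tested) {
      de_vec <- obs[[cid]]$de_vec
      wm_vec <- obs[[cid]]$wm_vec
      rx <- rank(de_vec); ry <- rank(wm_vec)
      rx <- rx - mean(rx)
      hits <- 0L
      for (b in seq_len(B)) {
        ryp <- ry[sample.int(length(ry))]
        ryp <- ryp - mean(ryp)
        den <- sqrt(sum(rx^2) * sum(ryp^2))
        if (den == 0) next
        if (sum(rx * ryp) / den >= obs[[cid]]$r_obs - 1e-12) hits <- hits + 1L
      }
      p_num <- if (hits == 0) 1 / B else hits / B
      rows[[cid]] <- data.frame(
        collection = cid, n_sets = length(de_vec), r_r = obs[[cid]]$r_obs,
        p = if (hits == 0) sprintf("<%g", 1 / B) else format(hits / B),
        p_num = p_num, B = B, stringsAsFactors = FALSE)
    }
  }

  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(collection = character(0), n_sets = integer(0),
               r_r = numeric(0), p = character(0), p_num = numeric(0),
               B = integer(0))
  rownames(out) <- NULL
  out <- adjust_collection_pvalues(out)
  attr(out, "details") <- details
  class(out) <- c("funcorr_result", "data.frame")
  out
}

#' Adjust per-collection permutation p-values across collections
#'
#' Benjamini-Hochberg over the tested collections (with `"<1/B"` entries
#' adjusted at their numeric bound `1/B`); rows are ordered by increasing p.
#'
#' @param results data frame with a `p_num` column (e.g. from
#'   [overlap_aware_permutation_test()]).
#' @return the same data frame with a `q` column, sorted by `p_num`.
#' @export
adjust_collection_pvalues <- function(results) {
  stopifnot(is.data.frame(results), "p_num" %in% names(results))
  results$q <- adjust_pvalues(results$p_num)
  results[order(results$p_num), , drop = FALSE]
}
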