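# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Mann-Whitney U by explicit pairwise comparison, ties worth 1/2
brute_force_rrb <- function(scores, membership) {
  m <- as.logical(membership)
  s1 <- scores[m]
  s0 <- scores[!m]
  u <- 0
  for (a in s1) for (b in s0) {
    u <- u + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  2 * u / (length(s1) * length(s0)) - 1
}

# all permutations of 1..n as a list (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Pearson correlation of midranks; NA when either side is constant
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

# mean pairwise Jaccard index over the sets of a collection
mean_pairwise_jaccard <- function(collection) {
  sets <- lapply(collection$sets, `[[`, "genes")
  n <- length(sets)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, length(intersect(sets[[i]], sets[[j]])) /
                length(union(sets[[i]], sets[[j]])))
  }
  mean(vals)
}

# small count matrix with hand-chosen genes: `extra` is a named list of
# per-gene count vectors over the 8 samples (2 tissues x 2 species x 2)
toy_counts <- function(extra = list(), n_background = 30, seed = 99) {
  set.seed(seed)
  samples <- data.frame(
    sample_id = c("T1_h1", "T1_h2", "T1_c1", "T1_c2",
                  "T2_h1", "T2_h2", "T2_c1", "T2_c2"),
    species = rep(c("human", "human", "chimp", "chimp"), 2),
    tissue = rep(c("T1", "T2"), each = 4),
    individual = rep(c("h1", "h2", "c1", "c2"), 2),
    stringsAsFactors = FALSE)
  bg <- matrix(rnbinom(n_background * 8, mu = 150, size = 10), n_background, 8)
  rownames(bg) <- sprintf("bg%03d", seq_len(n_background))
  mat <- rbind(bg, do.call(rbind, lapply(extra, as.integer)))
  colnames(mat) <- samples$sample_id
  storage.mode(mat) <- "integer"
  count_matrix(mat, samples)
}
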