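test_that("library-size offsets follow totals", {
  cm <- toy_counts()
  off <- normalize_offsets(cm)
  expect_equal(unname(off), unname(log(colSums(cm$counts))))

  # doubling every count shifts the offset by exactly ln 2
  doubled <- cm
  doubled$counts[, 1] <- 2L * cm$counts[, 1]
  cm2 <- count_matrix(doubled$counts, cm$samples)
  off2 <- normalize_offsets(cm2)
  expect_equal(off2[[1]] - off[[1]], log(2))
})

test_that("TMM factors are neutral for composition-identical samples", {
  cm <- toy_counts()
  mat <- cm$counts
  mat[, 2] <- 2L * mat[, 1]          # sample 2 = 2x sample 1 count-for-count
  cm <- count_matrix(mat, cm$samples)
  off_plain <- normalize_offsets(cm)
  off_tmm <- normalize_offsets(cm, tmm = TRUE)
  f <- exp(off_tmm - off_plain)      # TMM factors
  expect_equal(unname(f[2] / f[1]), 1, tolerance = 1e-6)

  # brute-force oracle: the trimmed mean of per-gene log proportion ratios
  # between the two samples is exactly 0, so their factors must agree
  p1 <- mat[, 1] / sum(mat[, 1])
  p2 <- mat[, 2] / sum(mat[, 2])
  expect_equal(mean(log2(p2 / p1), trim = 0.3), 0)
})

test_that("TMM factors track an independent implementation", {
  set.seed(31)
  mat <- matrix(rnbinom(200 * 8, mu = 300, size = 5), 200, 8)
  mat[1:20, 5] <- mat[1:20, 5] * 8L   # composition shift in one sample
  cm <- toy_counts()
  rownames(mat) <- sprintf("gene%03d", 1:200)
  colnames(mat) <- cm$samples$sample_id
  cm <- count_matrix(mat, cm$samples)
  ours <- exp(normalize_offsets(cm, tmm = TRUE) - normalize_offsets(cm))
  theirs <- edgeR::calcNormFactors(mat, method = "TMM")
  expect_gt(cor(log(ours), log(theirs)), 0.9)
})

test_that("all-zero samples are rejected", {
  cm <- toy_counts()
  mat <- cm$counts
  mat[, 3] <- 0L
  cm <- count_matrix(mat, cm$samples)
  expect_error(normalize_offsets(cm), "zero total")
})

test_that("Benjamini-Hochberg adjustment matches the hand-stepped values", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.5), 0.5)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  p <- runif(50)
  q <- adjust_pvalues(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))
})

test_that("DE scores are the negative log of adjusted p-values", {
  expect_equal(de_score(1), 0)
  expect_equal(de_score(exp(-1)), 1)
  expect_equal(de_score(0.05), 2.9957, tolerance = 1e-4)
  expect_equal(de_score(0), -log(1e-300))
  expect_error(de_score(0, floor = 0), "floor")
  # strictly decreasing in q
  q <- c(0.9, 0.5, 0.1, 0.01)
  expect_true(all(diff(de_score(q)) > 0))
})

test_that("effect-distribution comparison reproduces known KS statistics", {
  mk <- function(ti, sp) {
    d <- data.frame(q_tissue_effect = 10^-ti, q_overall = 10^-sp)
    class(d) <- c("de_result", "data.frame")
    d
  }
  same <- compare_effect_distributions(mk(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$D, 0)

  shifted <- compare_effect_distributions(mk(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(shifted$D, 1 / 3)
  expect_identical(shifted$direction, "species")

  disjoint <- compare_effect_distributions(mk(c(1, 2, 3), c(5, 6, 7)))
  expect_equal(disjoint$D, 1)
})

test_that("the GLM finds nothing for a gene identical across species", {
  flat <- rep(c(120L, 130L, 120L, 130L, 200L, 210L, 200L, 210L), 1)
  cm <- toy_counts(extra = list(flat_gene = flat))
  # equal offsets so that identical counts mean an identically zero contrast
  de <- fit_de_glm(cm, offsets = setNames(rep(10, 8), colnames(cm$counts)))
  row <- de[de$gene == "flat_gene", ]
  expect_gt(row$p_overall, 0.99)
  expect_true(row$converged)
})

test_that("all-zero genes are excluded from testing, not scored", {
  cm <- toy_counts(extra = list(zero_gene = rep(0L, 8)))
  de <- fit_de_glm(cm)
  row <- de[de$gene == "zero_gene", ]
  expect_true(is.na(row$p_overall))
  expect_false(row$converged)
})

test_that("a strong planted species effect is detected with a small q-value", {
  up <- c(100L, 110L, 800L, 820L, 150L, 140L, 1200L, 1150L)
  cm <- toy_counts(extra = list(up_gene = up))
  de <- fit_de_glm(cm)
  row <- de[de$gene == "up_gene", ]
  expect_lt(row$q_overall, 0.05)
  expect_equal(row$score_overall, -log(row$q_overall))
})

test_that("likelihood-ratio statistics are nonnegative across a simulated dataset", {
  cfg <- sim_config(n_genes = 300, n_collections = 1,
                    sets_per_collection = 2, set_size_range = c(10, 20),
                    coupling = 0, seed = 17)
  ds <- simulate_dataset(cfg)
  de <- fit_de_glm(ds$counts)
  ok <- !is.na(de$p_overall)
  expect_gt(mean(ok), 0.95)
  expect_true(all(de$p_overall[ok] >= 0 & de$p_overall[ok] <= 1))
  expect_true(all(de$q_overall[ok] >= de$p_overall[ok] - 1e-12))
  # score is strictly decreasing in q
  o <- order(de$q_overall[ok])
  expect_true(all(diff(de$score_overall[ok][o]) <= 1e-12))
})
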