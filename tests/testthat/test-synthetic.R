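small_cfg <- function(...) {
  sim_config(n_genes = 600, n_collections = 2, sets_per_collection = 6,
             set_size_range = c(10, 30), coupling = 0, ...)
}

test_that("identical seeds give bit-identical datasets", {
  a <- simulate_dataset(small_cfg(seed = 5))
  b <- simulate_dataset(small_cfg(seed = 5))
  expect_identical(a$counts, b$counts)
  expect_identical(a$collections, b$collections)
  expect_identical(lapply(a$adapt_tables, `[[`, "scores"),
                   lapply(b$adapt_tables, `[[`, "scores"))
  c <- simulate_dataset(small_cfg(seed = 6))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("counts respect the configured design", {
  cfg <- small_cfg(n_tissues = 3, n_per_species = 2, seed = 2)
  ds <- simulate_dataset(cfg)
  expect_identical(nrow(ds$counts$samples), 3L * 2L * 2L)
  expect_true(all(ds$counts$counts >= 0))
  expect_true(all(ds$counts$counts == round(ds$counts$counts)))
  expect_identical(sort(unique(ds$counts$samples$species)),
                   c("chimp", "human"))
})

test_that("frac_de = 0 plants no effects", {
  ds <- simulate_dataset(small_cfg(frac_de = 0, seed = 3))
  expect_length(ds$truth$de_genes, 0)
  expect_true(all(ds$truth$lfc == 0))
})

test_that("in the noiseless limit observed species log-ratios match planted effects", {
  cfg <- sim_config(n_genes = 1000, n_collections = 1,
                    sets_per_collection = 2, set_size_range = c(10, 20),
                    coupling = 0, dispersion = 0, baseline_sd_log = 0.3,
                    tissue_lfc_sd = 0, frac_de = 0,
                    library_size_range = c(5e6, 5e6), seed = 8)
  genes <- sprintf("g%05d", 1:1000)
  lfc <- matrix(0, 1000, 5, dimnames = list(genes, paste0("T", 1:5)))
  planted <- genes[1:10]
  lfc[planted, ] <- 1
  truth <- ground_truth(lfc)
  cnt <- simulate_counts(cfg, truth)$counts
  human <- cnt$samples$species == "human"
  obs <- log(rowMeans(cnt$counts[planted, !human]) /
             rowMeans(cnt$counts[planted, human]))
  expect_true(all(abs(obs - 1) < 0.1))
})

test_that("marginal counts obey the negative-binomial moment identity", {
  cfg <- sim_config(n_genes = 2000, n_collections = 1,
                    sets_per_collection = 2, set_size_range = c(10, 20),
                    coupling = 0, dispersion = 0.2, frac_de = 0,
                    tissue_lfc_sd = 0, baseline_sd_log = 1,
                    library_size_range = c(1e6, 1e6), seed = 4)
  cnt <- simulate_counts(cfg)$counts$counts
  m <- rowMeans(cnt)
  v <- apply(cnt, 1, var)
  keep <- m > 50          # Poisson term negligible relative to phi * mu^2
  phi_hat <- mean((v[keep] - m[keep]) / m[keep]^2)
  expect_lt(abs(phi_hat - 0.2) / 0.2, 0.2)
})

test_that("overlap exponent controls pairwise set overlap", {
  base <- sim_config(n_genes = 5000, n_collections = 1,
                     sets_per_collection = 8, set_size_range = c(10, 20),
                     coupling = 0, overlap_exponent = 0, seed = 9)
  disjointish <- simulate_gene_sets(base)[[1]]
  expect_lt(mean_pairwise_jaccard(disjointish), 0.02)

  heavy <- sim_config(n_genes = 5000, n_collections = 1,
                      sets_per_collection = 8, set_size_range = c(10, 20),
                      coupling = 0, overlap_exponent = 2, seed = 9)
  overlapping <- simulate_gene_sets(heavy)[[1]]
  expect_gt(mean_pairwise_jaccard(overlapping),
            mean_pairwise_jaccard(disjointish))
})

test_that("degenerate set layouts behave as specified", {
  one <- simulate_gene_sets(sim_config(n_genes = 200, n_collections = 1,
                                       sets_per_collection = 1,
                                       set_size_range = c(5, 10),
                                       coupling = 0, seed = 1))
  expect_length(one, 1)
  expect_length(one[[1]]$sets, 1)
  expect_error(sim_config(n_genes = 50, set_size_range = c(10, 60)),
               "exceeds")
})

test_that("full study coverage scores every gene", {
  ds <- simulate_dataset(small_cfg(study_coverage = 1, seed = 11))
  for (tab in ds$adapt_tables)
    expect_identical(names(tab$scores), sprintf("g%05d", 1:600))
})

test_that("uncoupled datasets carry no set-level DE-adaptation association", {
  cfg <- sim_config(n_genes = 4000, n_collections = 1,
                    sets_per_collection = 200, set_size_range = c(10, 30),
                    coupling = 0, seed = 13)
  ds <- simulate_dataset(cfg)
  de_eff <- rowMeans(abs(ds$truth$lfc))
  per_set <- t(vapply(ds$collections[[1]]$sets, function(s)
    c(mean(de_eff[s$genes]), mean(ds$truth$adapt_propensity[s$genes])),
    numeric(2)))
  expect_lt(abs(oracle_spearman(per_set[, 1], per_set[, 2])), 0.15)
})

test_that("coupling plants a recoverable set-level association", {
  cfg <- sim_config(n_genes = 3000, n_collections = 2,
                    sets_per_collection = 20, set_size_range = c(40, 80),
                    coupling = 2, study_noise_sd = 1, seed = 14)
  ds <- simulate_dataset(cfg)
  expect_identical(ds$truth$coupled_collections, "C1")
  de_eff <- rowMeans(abs(ds$truth$lfc))
  per_set <- t(vapply(ds$collections[[1]]$sets, function(s)
    c(mean(de_eff[s$genes]), mean(ds$truth$adapt_propensity[s$genes])),
    numeric(2)))
  expect_gt(oracle_spearman(per_set[, 1], per_set[, 2]), 0.5)
  # uncoupled collection drawn outside the coupled genes
  c1_genes <- unique(unlist(lapply(ds$collections[[1]]$sets, `[[`, "genes")))
  c2_genes <- unique(unlist(lapply(ds$collections[[2]]$sets, `[[`, "genes")))
  expect_length(intersect(c1_genes, c2_genes), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_de = 1.5), "frac_de")
  expect_error(sim_config(n_per_species = 1), "n_per_species")
  expect_error(sim_config(set_size_range = c(1, 10)), "set_size_range")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(baseline_mean_log = NaN), "finite")
  expect_error(sim_config(library_size_range = c(2e6, 1e6)),
               "library_size_range")
})

test_that("a simulated dataset writes and reads back from disk", {
  ds <- simulate_dataset(small_cfg(seed = 21))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_counts(file.path(dir, "counts.tsv"),
                      file.path(dir, "samples.tsv"))
  expect_identical(back$counts, ds$counts$counts)
  coll <- read_gmt(file.path(dir, "C1.gmt"))
  expect_identical(lapply(coll$sets, `[[`, "genes"),
                   lapply(ds$collections[[1]]$sets, `[[`, "genes"))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  sc <- read_scores(file.path(dir, "study1_scores.tsv"), "study1")
  expect_equal(sc$scores, signif(ds$adapt_tables[[1]]$scores, 6))
})
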