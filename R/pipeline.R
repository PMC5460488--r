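#' Run the full inference chain on a simulated dataset
#'
#' Convenience orchestration used by the analysis scripts and the validation
#' suite: simulate (or accept) a dataset, score differential expression with
#' the multi-factor NB GLM, compare tissue and species effect distributions,
#' compute tissue-specificity correlations, correlate gene-level scores, and
#' run the overlap-aware permutation test of the per-collection functional
#' correlations.
#'
#' @param config a [sim_config()]; ignored when `dataset` is supplied.
#' @param dataset optionally, a pre-built [simulate_dataset()] result.
#' @param B permutation replicates for the functional-correlation test.
#' @param boot_B bootstrap replicates for per-study enrichment SEs.
#' @param genic_B permutation replicates for the gene-level correlation
#'   (0 skips it).
#' @param min_genes,min_studies,alpha_q,min_mean_genes filters, see
#'   [overlap_aware_permutation_test()].
#' @param specificity compute the tissue-specificity analysis.
#' @param tmm use trimmed-mean normalization offsets.
#' @return list with elements `dataset`, `de`, `effect_comparison`,
#'   `specificity`, `genic`, `funcorr`.
#' @export
run_pipeline <- function(config = sim_config(), dataset = NULL, B = 2000,
                         boot_B = 200, genic_B = 2000, min_genes = 50,
                         min_studies = 2, alpha_q = 0.05,
                         min_mean_genes = 50, specificity = TRUE,
                         tmm = FALSE) {
  if (is.null(dataset)) dataset <- simulate_dataset(config)
  offsets <- normalize_offsets(dataset$counts, tmm = tmm)
  de <- fit_de_glm(dataset$counts, offsets,
                   contrasts = if (specificity) "all" else "overall")
  comparison <- if (specificity) compare_effect_distributions(de) else NULL
  spec <- if (specificity) specificity_analysis(de) else NULL
  de_table <- de_score_table(de)
  genic <- if (genic_B > 0)
    genic_correlation(de_table, dataset$adapt_tables[[1]], B = genic_B,
                      seed = derive_seed(dataset$config$seed, "genic_corr"))
  else NULL
  fc <- overlap_aware_permutation_test(
    de_table, dataset$adapt_tables, dataset$collections,
    min_genes = min_genes, B = B,
    seed = derive_seed(dataset$config$seed, "funcorr"), boot_B = boot_B,
    min_studies = min_studies, alpha_q = alpha_q,
    min_mean_genes = min_mean_genes)
  list(dataset = dataset, de = de, effect_comparison = comparison,
       specificity = spec, genic = genic, funcorr = fc)
}
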