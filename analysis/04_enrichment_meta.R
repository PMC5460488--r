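#!/usr/bin/env Rscript
# Step 4: rank-biserial enrichment of every sufficiently large gene set
# with (a) differential-expression scores and (b) each adaptation study's
# scores (with bootstrap SEs), then fixed-effects meta-combination of the
# adaptation enrichments across studies with Cochran heterogeneity and the
# n >= 2 / mean-genes >= 50 retention filters.

suppressPackageStartupMessages(library(funcorr))

de_table <- read_scores("results/de_score_table.tsv", "expression")
collections <- lapply(list.files("results/data", pattern = "^C\\d+\\.gmt$",
                                 full.names = TRUE), read_gmt)
studies <- lapply(list.files("results/data", pattern = "_scores\\.tsv$",
                             full.names = TRUE), function(p)
  read_scores(p, sub("_scores\\.tsv$", "", basename(p))))

seed <- 20240104
de_enr <- list()
meta <- list()
for (coll in collections) {
  cid <- coll$collection_id
  de_enr[[cid]] <- enrich_collection(de_table, coll, B = 1000, seed = seed)
  per_study <- lapply(studies, function(s)
    enrich_collection(s, coll, B = 1000,
                      seed = derive_seed(seed, s$study_id)))
  meta[[cid]] <- combine_studies(per_study)
  cat(sprintf("%s: %d sets enriched for DE; %d/%d retained after meta filters\n",
              cid, nrow(de_enr[[cid]]), sum(meta[[cid]]$retained),
              nrow(meta[[cid]])))
}

de_all <- do.call(rbind, de_enr)
cat("\nTop sets by enrichment with differential expression:\n")
print(head(de_all[order(-de_all$r_rb),
                  c("set", "collection", "n_genes", "r_rb", "se")], 5),
      row.names = FALSE)

write_results(list(enrichment_de = de_all,
                   meta_adaptation = do.call(rbind, meta)), "results")
cat("Wrote results/enrichment_de.tsv and results/meta_adaptation.tsv\n")
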