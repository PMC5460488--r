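#!/usr/bin/env Rscript
# Step 3: squared-cosine tissue specificity of the per-tissue differential
# expression scores, and its correlation with per-tissue divergence.

suppressPackageStartupMessages(library(funcorr))

counts <- read_counts("results/data/counts.tsv", "results/data/samples.tsv")
de <- fit_de_glm(counts)
spec <- specificity_analysis(de)

cat("Per-tissue Spearman correlation between tissue specificity of",
    "differential expression and the tissue's divergence score:\n")
print(spec$summary, row.names = FALSE)

profile <- data.frame(gene = rownames(spec$profile), spec$profile,
                      check.names = FALSE)
write_results(list(specificity_profile = profile,
                   specificity_summary = spec$summary), "results")
cat("Wrote results/specificity_profile.tsv and results/specificity_summary.tsv\n")
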