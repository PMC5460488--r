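#' Per-sample log offsets for the NB GLM
#'
#' Library-size offsets `log(total count)` by default; with `tmm = TRUE` a
#' trimmed-mean-of-M-values style factor (per-gene log ratios to a reference
#' sample, trimmed 30% on M and 5% on A, averaged) multiplies the library
#' size, correcting for composition differences.
#'
#' @param counts a [count_matrix()].
#' @param tmm apply the trimmed-mean adjustment.
#' @param trim_m,trim_a two-sided trim fractions on the log-ratio (M) and
#'   average-abundance (A) scales.
#' @return named numeric vector of per-sample log offsets.
#' @export
normalize_offsets <- function(counts, tmm = FALSE, trim_m = 0.3,
                              trim_a = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- colSums(counts$counts)
  if (any(totals <= 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts$counts)[totals <= 0], collapse = ", "),
         call. = FALSE)
  offsets <- log(totals)
  if (tmm) {
    p <- sweep(counts$counts, 2, totals, "/")
    # reference: sample whose upper quartile is closest to the median one
    uq <- apply(p, 2, quantile, probs = 0.75)
    ref <- which.min(abs(uq - median(uq)))
    f <- vapply(seq_len(ncol(p)), function(j) {
      keep <- p[, j] > 0 & p[, ref] > 0
      if (!any(keep)) return(1)
      M <- log2(p[keep, j] / p[keep, ref])
      A <- 0.5 * log2(p[keep, j] * p[keep, ref])
      lo_m <- quantile(M, trim_m); hi_m <- quantile(M, 1 - trim_m)
      lo_a <- quantile(A, trim_a); hi_a <- quantile(A, 1 - trim_a)
      use <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
      if (!any(use)) return(1)
      2^mean(M[use])
    }, numeric(1))
    f <- f / exp(mean(log(f)))         # factors multiply to 1
    offsets <- offsets + log(f)
  }
  setNames(offsets, colnames(counts$counts))
}

# Method-of-moments NB dispersion per gene, shrunk 50/50 toward the common
# (across-gene ratio-of-sums) dispersion.  Counts are rescaled to a common
# library size first; moments are taken within species x tissue cells.
estimate_dispersions <- function(counts, offsets) {
  y <- sweep(counts$counts, 2, exp(offsets - mean(offsets)), "/")
  cell <- interaction(counts$samples$species, counts$samples$tissue,
                      drop = TRUE)
  num <- den <- numeric(nrow(y))
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    n_c <- length(idx)
    m <- rowMeans(y[, idx, drop = FALSE])
    v <- (rowSums(y[, idx, drop = FALSE]^2) - n_c * m^2) / (n_c - 1)
    num <- num + (v - m)
    # E[m^2] = mu^2 + var(m); subtract v/n so the denominator is an
    # unbiased estimate of mu^2 (otherwise phi is biased downward)
    den <- den + pmax(m^2 - v / length(idx), m^2 / 2)
  }
  phi_gene <- pmax(num / pmax(den, 1e-12), 0)
  # unweighted mean across genes: inverse-variance-style weighting by the
  # denominator is biased downward because the weight and the estimate share
  # the same variance noise
  phi_common <- max(mean(phi_gene[is.finite(phi_gene)]), 1e-4)
  phi <- pmax(0.5 * phi_gene + 0.5 * phi_common, 1e-4)
  list(phi = setNames(phi, rownames(y)), common = phi_common,
       phi_gene = phi_gene)
}

#' Multi-factor NB GLM differential-expression scoring
#'
#' Fits, per gene, the negative-binomial log-linear model
#' `log mu = offset + tissue + species + tissue:species` with a fixed
#' per-gene dispersion (method-of-moments estimate shrunk 50/50 toward the
#' common dispersion). The overall species p-value is a likelihood-ratio
#' test of the full model against the model with every species-related
#' coefficient removed; per-tissue species p-values are Wald tests of the
#' within-tissue species contrast; the tissue p-value drops the tissue
#' main-effect columns. Adjusted values use Benjamini-Hochberg and scores
#' are `-ln` of the adjusted values.
#'
#' @param counts a [count_matrix()] with at least 2 samples per
#'   species-by-tissue cell.
#' @param offsets per-sample log offsets from [normalize_offsets()];
#'   computed with defaults when omitted.
#' @param contrasts `"all"` (default) fits every contrast; `"overall"` fits
#'   only the overall species test (cheaper when per-tissue and tissue-factor
#'   results are not needed).
#' @return a `de_result` data frame, one row per gene: `gene`, `p_overall`,
#'   `q_overall`, `score_overall`, `p_tissue_effect`, `q_tissue_effect`,
#'   `score_tissue_effect`, per-tissue `p_<t>`/`q_<t>`/`score_<t>` columns,
#'   `dispersion`, `converged`. Genes with all-zero counts (or
#'   non-convergent fits) carry `NA` p-values.
#' @export
fit_de_glm <- function(counts, offsets = NULL,
                       contrasts = c("all", "overall")) {
  contrasts <- match.arg(contrasts)
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(offsets)) offsets <- normalize_offsets(counts)
  samples <- counts$samples
  tissues <- sort(unique(samples$tissue))
  species <- factor(samples$species,
                    levels = c("human", setdiff(unique(samples$species),
                                                "human")))
  tissue <- factor(samples$tissue, levels = tissues)
  tab <- table(species, tissue)
  if (any(tab < 2))
    stop("need >= 2 samples in every species x tissue cell", call. = FALSE)

  expressed <- rowSums(counts$counts) > 0
  Y <- t(counts$counts[expressed, , drop = FALSE]) * 1.0

  disp <- estimate_dispersions(counts, offsets)
  phi <- disp$phi[expressed]
  theta <- 1 / phi

  # cell-means parameterization: per-tissue baselines plus a within-tissue
  # species contrast for each tissue (same span as tissue*species)
  X_full <- model.matrix(~ 0 + tissue + tissue:species)
  X_red_species <- model.matrix(~ 0 + tissue)
  X_std <- model.matrix(~ tissue + species + tissue:species)
  tissue_main_cols <- grep("^tissue", colnames(X_std))
  tissue_main_cols <- setdiff(tissue_main_cols, grep(":", colnames(X_std)))
  X_red_tissue <- X_std[, -tissue_main_cols, drop = FALSE]

  off <- as.numeric(offsets)
  want_all <- contrasts == "all"
  fit_full <- nbglm_fit_batch(Y, X_full, off, theta, want_coef = want_all)
  fit_red_sp <- nbglm_fit_batch(Y, X_red_species, off, theta)
  ok <- fit_full$converged & fit_red_sp$converged
  lrt_sp <- pmax(fit_red_sp$deviance - fit_full$deviance, 0)
  df_sp <- ncol(X_full) - ncol(X_red_species)
  p_overall <- ifelse(ok, pchisq(lrt_sp, df_sp, lower.tail = FALSE), NA_real_)

  genes <- rownames(counts$counts)
  full_na <- rep(NA_real_, length(genes))
  res <- data.frame(gene = genes, p_overall = full_na,
                    stringsAsFactors = FALSE)
  res$p_overall[expressed] <- p_overall
  res$q_overall <- adjust_pvalues(res$p_overall)
  res$score_overall <- de_score(res$q_overall)

  if (want_all) {
    fit_red_ti <- nbglm_fit_batch(Y, X_red_tissue, off, theta)
    ok_ti <- ok & fit_red_ti$converged
    lrt_ti <- pmax(fit_red_ti$deviance - fit_full$deviance, 0)
    df_ti <- length(tissue_main_cols)
    p_tissue_effect <- ifelse(ok_ti, pchisq(lrt_ti, df_ti, lower.tail = FALSE),
                              NA_real_)
    int_cols <- grep(":", colnames(X_full))
    names(int_cols) <- sub("^tissue([^:]+):.*$", "\\1",
                           colnames(X_full)[int_cols])
    p_tissue <- sapply(tissues, function(t) {
      j <- int_cols[[t]]
      z <- fit_full$coef[j, ] / fit_full$se[j, ]
      ifelse(ok, 2 * pnorm(-abs(z)), NA_real_)
    })
    p_tissue <- matrix(p_tissue, ncol = length(tissues),
                       dimnames = list(NULL, tissues))
    res$p_tissue_effect <- full_na
    res$p_tissue_effect[expressed] <- p_tissue_effect
    res$q_tissue_effect <- adjust_pvalues(res$p_tissue_effect)
    res$score_tissue_effect <- de_score(res$q_tissue_effect)
    for (t in tissues) {
      p <- full_na
      p[expressed] <- p_tissue[, t]
      q <- adjust_pvalues(p)
      res[[paste0("p_", t)]] <- p
      res[[paste0("q_", t)]] <- q
      res[[paste0("score_", t)]] <- de_score(q)
    }
  }
  res$dispersion <- NA_real_
  res$dispersion[expressed] <- phi
  res$converged <- FALSE
  res$converged[expressed] <- ok
  attr(res, "tissues") <- tissues
  attr(res, "dispersion_common") <- disp$common
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA` values are propagated and do not count
#' toward the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted values, pointwise `>= p` and monotone in `p`.
#' @export
adjust_pvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Differential-expression score from an adjusted p-value
#'
#' `score = -ln(q)`, with `q` floored at `1e-300` so a reported zero cannot
#' produce an infinite score (ranking unaffected).
#'
#' @param q adjusted p-values in `[0, 1]` (`NA` allowed).
#' @param floor lower clamp applied before the logarithm.
#' @return nonnegative scores.
#' @export
de_score <- function(q, floor = 1e-300) {
  if (any(q < 0 | q > 1, na.rm = TRUE))
    stop("adjusted p-values must lie in [0, 1]", call. = FALSE)
  if (floor <= 0 && any(q == 0, na.rm = TRUE))
    stop("q = 0 cannot be scored without a positive floor", call. = FALSE)
  -log(pmax(q, floor))
}

#' Compare the tissue and species effect-size distributions
#'
#' Two-sample Kolmogorov-Smirnov test between the `-log10` adjusted-p
#' distributions of the tissue factor and the overall species contrast,
#' asking which factor explains more differential expression.
#'
#' @param de a [fit_de_glm()] result.
#' @return `list(D =, p =, direction =)` where `direction` names the factor
#'   whose `-log10(q)` distribution is stochastically larger.
#' @export
compare_effect_distributions <- function(de) {
  stopifnot(inherits(de, "de_result"))
  x <- -log10(pmax(de$q_tissue_effect, 1e-300))
  y <- -log10(pmax(de$q_overall, 1e-300))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("empty effect distribution", call. = FALSE)
  ks <- suppressWarnings(ks.test(x, y))
  pooled_ranks <- rank(c(x, y))
  direction <- if (mean(pooled_ranks[seq_along(x)]) >=
                   mean(pooled_ranks[-seq_along(x)])) "tissue" else "species"
  list(D = unname(ks$statistic), p = ks$p.value, direction = direction)
}

#' Turn a DE result into a per-gene score table
#'
#' @param de a [fit_de_glm()] result.
#' @param column which score column to extract (default the overall species
#'   score).
#' @return a [gene_score_table()] over the genes with defined scores.
#' @export
de_score_table <- function(de, column = "score_overall") {
  stopifnot(inherits(de, "de_result"), column %in% names(de))
  keep <- !is.na(de[[column]])
  gene_score_table("expression", setNames(de[[column]][keep], de$gene[keep]))
}
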