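#' Squared-cosine tissue-specificity scores
#'
#' For each gene's nonnegative vector over tissues, the specificity score
#' for tissue `t` is the squared cosine of the angle between the vector and
#' the `t` axis: `s_t = x_t^2 / sum_j x_j^2`. Scores depend on the
#' distribution of signal over tissues, not its magnitude; a gene expressed
#' in a single tissue scores 1 there and 0 elsewhere, a uniformly expressed
#' gene scores `1/n_tissues` everywhere.
#'
#' @param mat gene x tissue matrix of finite nonnegative values (e.g.
#'   per-tissue differential-expression scores, or mean expression).
#' @return matrix of the same shape; rows sum to 1, except all-zero input
#'   rows which are returned as `NA` (flagged, not 0/0).
#' @export
specificity_scores <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("entries must be finite", call. = FALSE)
  if (any(mat < 0)) stop("entries must be nonnegative", call. = FALSE)
  sq <- mat^2
  tot <- rowSums(sq)
  out <- sq / tot                      # 0/0 -> NaN for all-zero rows
  out[tot == 0, ] <- NA_real_
  out
}

#' Correlation between tissue specificity and expression divergence
#'
#' Spearman correlation, over the genes shared by both inputs, between the
#' specificity score for one tissue and a per-gene divergence score for that
#' tissue (typically the per-tissue differential-expression score).
#'
#' @param profile matrix from [specificity_scores()] with gene row names.
#' @param tissue column of `profile` to use.
#' @param divergence named per-gene divergence scores.
#' @return `list(rho =, p =, n =)`; `rho` is `NA` when either vector is
#'   constant on the intersection.
#' @export
specificity_divergence_correlation <- function(profile, tissue, divergence) {
  stopifnot(tissue %in% colnames(profile), !is.null(names(divergence)))
  s <- profile[, tissue]
  genes <- intersect(rownames(profile)[!is.na(s)],
                     names(divergence)[!is.na(divergence)])
  if (length(genes) < 10)
    stop("need >= 10 genes shared between profile and divergence scores",
         call. = FALSE)
  x <- s[genes]
  y <- divergence[genes]
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(genes)))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(genes))
}

#' Per-tissue specificity-divergence summary for a DE result
#'
#' Builds the specificity profile from the per-tissue DE score columns of a
#' [fit_de_glm()] result (or, optionally, from mean expression by tissue)
#' and correlates each tissue's specificity with that tissue's DE score.
#'
#' @param de a [fit_de_glm()] result.
#' @param counts optional [count_matrix()]; when supplied with
#'   `input = "expression"`, mean normalized expression by tissue is used as
#'   the profile input instead of DE scores.
#' @param input `"de_score"` (default) or `"expression"`.
#' @return `list(profile =, summary =)` where `summary` is a data frame of
#'   per-tissue `rho`, `p` and `n`.
#' @export
specificity_analysis <- function(de, counts = NULL,
                                 input = c("de_score", "expression")) {
  input <- match.arg(input)
  tissues <- attr(de, "tissues")
  if (input == "de_score") {
    mat <- as.matrix(de[, paste0("score_", tissues)])
    colnames(mat) <- tissues
    rownames(mat) <- de$gene
    mat <- mat[complete.cases(mat), , drop = FALSE]
  } else {
    stopifnot(inherits(counts, "count_matrix"))
    offsets <- normalize_offsets(counts)
    y <- sweep(counts$counts, 2, exp(offsets - mean(offsets)), "/")
    mat <- vapply(tissues, function(t)
      rowMeans(y[, counts$samples$tissue == t, drop = FALSE]),
      numeric(nrow(y)))
  }
  profile <- specificity_scores(mat)
  summary <- do.call(rbind, lapply(tissues, function(t) {
    div <- setNames(de[[paste0("score_", t)]], de$gene)
    res <- specificity_divergence_correlation(profile, t, div)
    data.frame(tissue = t, rho = res$rho, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  }))
  list(profile = profile, summary = summary)
}
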