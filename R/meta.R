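#' Inverse-variance weighted mean of per-study estimates
#'
#' Fixed-effects combination: `WM = sum_i w_i r_i` with
#' `w_i = (1/se_i)^2 / sum_j (1/se_j)^2`.
#'
#' @param r per-study estimates.
#' @param se per-study standard errors, all `> 0`.
#' @return `list(wm =, weights =)`; the weights sum to 1.
#' @export
weighted_mean_estimate <- function(r, se) {
  if (length(r) != length(se) || length(r) < 1)
    stop("'r' and 'se' must be equal-length, non-empty", call. = FALSE)
  if (any(!is.finite(r)) || any(!is.finite(se)))
    stop("estimates and standard errors must be finite", call. = FALSE)
  if (any(se <= 0))
    stop("all standard errors must be > 0 (floor degenerate bootstrap SEs ",
         "before combining)", call. = FALSE)
  w <- (1 / se)^2
  w <- w / sum(w)
  list(wm = sum(w * r), weights = w)
}

#' Cochran heterogeneity statistic for per-study estimates
#'
#' `Q = sum_i v_i (r_i - WM)^2`, approximately chi-squared with `n - 1`
#' degrees of freedom under homogeneity. By default the `v_i` are the
#' unnormalized inverse variances `1/se_i^2` (Cochran's form, under which the
#' chi-squared reference holds); `normalized = TRUE` reuses the weights that
#' sum to one instead.
#'
#' @inheritParams weighted_mean_estimate
#' @param normalized use normalized weights in the quadratic form.
#' @return `list(Q =, df =, p_q =)`.
#' @export
heterogeneity_q <- function(r, se, normalized = FALSE) {
  if (length(r) < 2) stop("heterogeneity needs n >= 2 studies", call. = FALSE)
  wm <- weighted_mean_estimate(r, se)$wm
  v <- (1 / se)^2
  if (normalized) v <- v / sum(v)
  Q <- sum(v * (r - wm)^2)
  df <- length(r) - 1L
  list(Q = Q, df = df, p_q = pchisq(Q, df, lower.tail = FALSE))
}

#' Combine per-study enrichment results across studies
#'
#' Matches sets by id across the per-study enrichment tables, computes the
#' inverse-variance weighted mean of `r_rb` with Cochran's heterogeneity
#' test, and applies the meta-analytic inclusion filters: a set is retained
#' iff it is present in at least `min_studies` studies, its heterogeneity is
#' not significant (`p_q > alpha_q`), and it contains at least
#' `min_mean_genes` measured genes on average over the studies that scored
#' it.
#'
#' @param per_study list of [enrich_collection()] data frames, one per study.
#' @param min_studies minimum number of studies a set must appear in
#'   (default 2).
#' @param alpha_q significance level for the heterogeneity filter
#'   (default 0.05).
#' @param min_mean_genes minimum mean per-study measured gene count
#'   (default 50).
#' @param se_floor lower bound applied to SEs before weighting, so a
#'   degenerate bootstrap SE of zero cannot produce an infinite weight.
#' @param normalized_q pass-through to [heterogeneity_q()].
#' @return data frame with one row per set appearing anywhere: `set`,
#'   `collection`, `n_studies`, `wm`, `Q`, `df`, `p_q`, `mean_genes`,
#'   `retained`, plus per-study weights in attribute `weights` (a named
#'   list of named vectors).
#' @export
combine_studies <- function(per_study, min_studies = 2, alpha_q = 0.05,
                            min_mean_genes = 50, se_floor = 1e-6,
                            normalized_q = FALSE) {
  stopifnot(is.list(per_study), length(per_study) >= 1)
  all_sets <- unique(unlist(lapply(per_study, function(d) d$set)))
  if (length(all_sets) == 0) {
    out <- data.frame(set = character(0), collection = character(0),
                      n_studies = integer(0), wm = numeric(0), Q = numeric(0),
                      df = integer(0), p_q = numeric(0),
                      mean_genes = numeric(0), retained = logical(0))
    attr(out, "weights") <- list()
    return(out)
  }
  weights <- list()
  rows <- vector("list", length(all_sets))
  for (k in seq_along(all_sets)) {
    s <- all_sets[k]
    r <- se <- ng <- numeric(0)
    study_idx <- integer(0)
    coll <- NA_character_
    for (i in seq_along(per_study)) {
      d <- per_study[[i]]
      j <- match(s, d$set)
      if (is.na(j)) next
      r <- c(r, d$r_rb[j]); se <- c(se, max(d$se[j], se_floor))
      ng <- c(ng, d$n_genes[j]); study_idx <- c(study_idx, i)
      coll <- d$collection[j]
    }
    n <- length(r)
    wm_fit <- weighted_mean_estimate(r, se)
    if (n >= 2) {
      het <- heterogeneity_q(r, se, normalized = normalized_q)
    } else {
      het <- list(Q = 0, df = 0L, p_q = NA_real_)
    }
    mean_genes <- mean(ng)
    retained <- n >= min_studies && (is.na(het$p_q) || het$p_q > alpha_q) &&
      mean_genes >= min_mean_genes
    if (n < min_studies) retained <- FALSE
    weights[[s]] <- setNames(wm_fit$weights, paste0("study", study_idx))
    rows[[k]] <- data.frame(set = s, collection = coll, n_studies = n,
                            wm = wm_fit$wm, Q = het$Q, df = het$df,
                            p_q = het$p_q, mean_genes = mean_genes,
                            retained = retained, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "weights") <- weights
  out
}
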