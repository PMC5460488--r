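#' Configuration for the synthetic-data generator
#'
#' Defines the conditions the generator emulates: a two-species (human /
#' chimpanzee-like) multi-tissue RNA-Seq design with negative-binomial counts
#' and tissue, species and species-within-tissue effects; overlapping gene-set
#' collections of heterogeneous size; and several "studies" of per-gene
#' adaptation scores with partial coverage and between-study heterogeneity.
#' A latent per-set effect shared between differential-expression propensity
#' and adaptation scores (`coupling`) plants the set-level signal the
#' downstream pipeline is built to recover.
#'
#' @param n_genes number of genes.
#' @param n_tissues number of tissues (five, as in a typical multi-tissue
#'   primate design).
#' @param n_per_species individuals per species; each individual contributes
#'   one sample per tissue.
#' @param baseline_mean_log,baseline_sd_log log-scale mean and spread of the
#'   per-gene baseline expression intensity.
#' @param dispersion negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`).
#' @param frac_de baseline proportion of genes with a planted species effect.
#' @param lfc_sd scale of planted species log-fold changes.
#' @param tissue_specific_frac proportion of planted genes whose species
#'   effect is confined to a single tissue.
#' @param tissue_lfc_sd scale of per-gene per-tissue baseline effects (makes
#'   tissue the dominant factor, as in real multi-tissue data).
#' @param library_size_range range of per-sample library sizes.
#' @param n_collections,sets_per_collection,set_size_range gene-set layout.
#' @param overlap_exponent Zipf popularity exponent controlling how strongly
#'   sets within a cluster share popular genes; 0 gives near-disjoint sets.
#' @param cluster_size number of sets sharing one popularity ordering.
#'   Curated databases contain families of closely related, redundant sets;
#'   clustered overlap is what makes naive set-level permutation
#'   anti-conservative, so the generator reproduces it.
#' @param n_studies number of adaptation-score studies.
#' @param study_coverage proportion of genes each study scores (subsets drawn
#'   independently across studies).
#' @param study_noise_sd per-study measurement noise on adaptation scores.
#' @param heterogeneity_sd between-study spread of a gene's adaptation signal.
#' @param coupling kappa, strength of the shared latent set-level effect on
#'   both differential expression and adaptation; 0 gives a pure null.
#' @param seed master seed; streamed to independent sub-generators for
#'   counts, sets, planted effects and scores.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 8000, n_tissues = 5, n_per_species = 4,
                       baseline_mean_log = 3, baseline_sd_log = 1.5,
                       dispersion = 0.1, frac_de = 0.3, lfc_sd = 1,
                       tissue_specific_frac = 0.3, tissue_lfc_sd = 1,
                       library_size_range = c(8e5, 1.2e6),
                       n_collections = 3, sets_per_collection = 60,
                       set_size_range = c(100, 250), overlap_exponent = 1,
                       cluster_size = 6,
                       n_studies = 3, study_coverage = 0.8,
                       study_noise_sd = 1, heterogeneity_sd = 0.25,
                       coupling = 0.6, seed = 1) {
  cfg <- list(n_genes = n_genes, n_tissues = n_tissues,
              n_per_species = n_per_species,
              baseline_mean_log = baseline_mean_log,
              baseline_sd_log = baseline_sd_log, dispersion = dispersion,
              frac_de = frac_de, lfc_sd = lfc_sd,
              tissue_specific_frac = tissue_specific_frac,
              tissue_lfc_sd = tissue_lfc_sd,
              library_size_range = as.numeric(library_size_range),
              n_collections = n_collections,
              sets_per_collection = sets_per_collection,
              set_size_range = as.integer(set_size_range),
              overlap_exponent = overlap_exponent,
              cluster_size = cluster_size, n_studies = n_studies,
              study_coverage = study_coverage,
              study_noise_sd = study_noise_sd,
              heterogeneity_sd = heterogeneity_sd, coupling = coupling,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (nm in setdiff(names(cfg), c("library_size_range", "set_size_range"))) {
    assert_scalar_number(cfg[[nm]], nm)
  }
  for (nm in c("n_genes", "n_tissues", "n_per_species", "n_collections",
               "sets_per_collection", "cluster_size", "n_studies"))
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]]))
      stop("'", nm, "' must be a positive integer", call. = FALSE)
  for (nm in c("frac_de", "tissue_specific_frac", "study_coverage"))
    assert_probability(cfg[[nm]], nm)
  for (nm in c("dispersion", "overlap_exponent", "coupling",
               "study_noise_sd", "heterogeneity_sd", "baseline_sd_log",
               "tissue_lfc_sd"))
    assert_scalar_number(cfg[[nm]], nm, lower = 0)
  assert_scalar_number(cfg$lfc_sd, "lfc_sd", lower = 1e-12)
  if (cfg$n_per_species < 2)
    stop("'n_per_species' must be >= 2", call. = FALSE)
  if (length(cfg$library_size_range) != 2 ||
      any(!is.finite(cfg$library_size_range)) ||
      any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    stop("'library_size_range' must be an increasing pair of positive reals",
         call. = FALSE)
  if (length(cfg$set_size_range) != 2 || any(is.na(cfg$set_size_range)) ||
      cfg$set_size_range[1] < 2 || diff(cfg$set_size_range) < 0)
    stop("'set_size_range' must be an increasing pair with min >= 2",
         call. = FALSE)
  if (cfg$set_size_range[2] > cfg$n_genes)
    stop("largest set size exceeds 'n_genes'", call. = FALSE)
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate overlapping gene-set collections
#'
#' Genes are sampled into sets with Zipf popularity weights (weight of the
#' gene with popularity rank r proportional to `r^-overlap_exponent`, with an
#' independent popularity ordering per collection), so a typical gene belongs
#' to several sets when the exponent is large, as in curated set databases.
#'
#' When `coupling > 0` the first collection will carry the planted coupling
#' ([plant_effects()]), and the remaining collections are drawn from the
#' genes outside it. This keeps them an exact null for the set-level
#' analysis: the emulated phenomenon is a function-specific co-enrichment
#' signal without a genome-wide gene-level correlation, and a validation
#' suite needs uncoupled collections whose rejection rate can be read as a
#' false-positive rate.
#'
#' @param config a [sim_config()].
#' @return list of [gene_set_collection()] objects (`C1`, `C2`, ...).
#' @export
simulate_gene_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_ids(config$n_genes)
  set.seed(derive_seed(config$seed, "gene_sets"))
  pool <- genes
  out <- vector("list", config$n_collections)
  for (ci in seq_len(config$n_collections)) {
    if (length(pool) < config$set_size_range[2])
      stop("gene pool too small for the requested set sizes; increase ",
           "'n_genes' or shrink the coupled collection", call. = FALSE)
    n_pool <- length(pool)
    n_sets <- config$sets_per_collection
    n_clusters <- ceiling(n_sets / config$cluster_size)
    cluster_of <- rep(seq_len(n_clusters),
                      each = config$cluster_size)[seq_len(n_sets)]
    cluster_weights <- lapply(seq_len(n_clusters), function(k) {
      pop <- sample(n_pool)                            # popularity ordering
      w <- numeric(n_pool)
      w[pop] <- seq_len(n_pool)^(-config$overlap_exponent)
      w
    })
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    n_sets, replace = TRUE)
    sets <- lapply(seq_len(n_sets), function(si) {
      list(description = sprintf("synthetic set %d of collection %d", si, ci),
           genes = sort(sample(pool, sizes[si],
                               prob = cluster_weights[[cluster_of[si]]])))
    })
    names(sets) <- sprintf("C%d_S%03d", ci, seq_len(config$sets_per_collection))
    out[[ci]] <- gene_set_collection(sprintf("C%d", ci), sets)
    if (ci == 1 && config$coupling > 0) {
      used <- unique(unlist(lapply(sets, `[[`, "genes")))
      pool <- setdiff(pool, used)
    }
  }
  out
}

#' Plant ground-truth effects shared between expression and adaptation
#'
#' Draws a latent nonnegative effect for every set of the coupled collection
#' (the first collection, when `coupling > 0`), propagates it to member genes
#' as an elevated differential-expression propensity and log-fold-change
#' magnitude, and stores the same latent signal as each gene's adaptation
#' propensity. With `coupling = 0` nothing is shared and the dataset is a
#' null for every set-level analysis.
#'
#' @param config a [sim_config()].
#' @param collections output of [simulate_gene_sets()].
#' @return a `ground_truth` list: `de_genes`, per-gene per-tissue `lfc`
#'   matrix, `tissue_confined`, per-set `set_effects`, `coupled_collections`,
#'   per-gene latent `adapt_propensity` and coupling field `z`.
#' @export
plant_effects <- function(config, collections) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_ids(config$n_genes)
  tissues <- sprintf("T%d", seq_len(config$n_tissues))
  set.seed(derive_seed(config$seed, "effects"))

  coupled <- character(0)
  if (config$coupling > 0 && length(collections) >= 1)
    coupled <- collections[[1]]$collection_id
  set_effects <- lapply(collections, function(coll) {
    e <- if (coll$collection_id %in% coupled)
      abs(rnorm(length(coll$sets))) else numeric(length(coll$sets))
    setNames(e, names(coll$sets))
  })
  names(set_effects) <- vapply(collections, `[[`, "", "collection_id")

  # per-gene latent coupling signal: kappa x mean effect of the gene's
  # coupled sets (0 for genes in none)
  z <- setNames(numeric(config$n_genes), genes)
  if (length(coupled) > 0) {
    acc <- setNames(numeric(config$n_genes), genes)
    cnt <- setNames(numeric(config$n_genes), genes)
    for (coll in collections) {
      if (!coll$collection_id %in% coupled) next
      eff <- set_effects[[coll$collection_id]]
      for (nm in names(coll$sets)) {
        g <- coll$sets[[nm]]$genes
        acc[g] <- acc[g] + eff[nm]
        cnt[g] <- cnt[g] + 1
      }
    }
    nz <- cnt > 0
    z[nz] <- config$coupling * acc[nz] / cnt[nz]
  }

  p_de <- plogis(qlogis(config$frac_de) + z)
  is_de <- rbinom(config$n_genes, 1, p_de) == 1
  de_genes <- genes[is_de]

  lfc <- matrix(0, config$n_genes, config$n_tissues,
                dimnames = list(genes, tissues))
  tissue_confined <- setNames(rep(NA_character_, config$n_genes), genes)
  if (any(is_de)) {
    mag <- abs(rnorm(sum(is_de), 0, config$lfc_sd)) + 0.3 * z[de_genes]
    sgn <- sample(c(-1, 1), sum(is_de), replace = TRUE)
    confined <- rbinom(sum(is_de), 1, config$tissue_specific_frac) == 1
    conf_tissue <- sample(tissues, sum(is_de), replace = TRUE)
    for (i in seq_along(de_genes)) {
      g <- de_genes[i]
      if (confined[i]) {
        lfc[g, conf_tissue[i]] <- sgn[i] * mag[i]
        tissue_confined[g] <- conf_tissue[i]
      } else {
        lfc[g, ] <- sgn[i] * mag[i]
      }
    }
  }

  adapt <- setNames(z + rnorm(config$n_genes), genes)
  structure(list(de_genes = de_genes, lfc = lfc,
                 tissue_confined = tissue_confined,
                 set_effects = set_effects, coupled_collections = coupled,
                 adapt_propensity = adapt, z = z),
            class = "ground_truth")
}

#' Construct a custom ground truth
#'
#' Builds a `ground_truth` object directly from a planted log-fold-change
#' matrix, for experiments that need exact effect sizes rather than the
#' randomized planting of [plant_effects()].
#'
#' @param lfc gene x tissue matrix of planted species log-fold changes, with
#'   gene ids as row names and tissue labels as column names.
#' @param adapt_propensity optional named per-gene latent adaptation scores
#'   (defaults to zero).
#' @return a `ground_truth` usable with [simulate_counts()] and
#'   [simulate_adaptation_scores()].
#' @export
ground_truth <- function(lfc, adapt_propensity = NULL) {
  stopifnot(is.matrix(lfc), !is.null(rownames(lfc)), !is.null(colnames(lfc)))
  genes <- rownames(lfc)
  if (is.null(adapt_propensity))
    adapt_propensity <- setNames(numeric(length(genes)), genes)
  stopifnot(identical(names(adapt_propensity), genes))
  de <- genes[rowSums(lfc != 0) > 0]
  confined <- apply(lfc, 1, function(r) {
    nz <- which(r != 0)
    if (length(nz) == 1) colnames(lfc)[nz] else NA_character_
  })
  structure(list(de_genes = de, lfc = lfc,
                 tissue_confined = setNames(confined, genes),
                 set_effects = list(), coupled_collections = character(0),
                 adapt_propensity = adapt_propensity,
                 z = setNames(numeric(length(genes)), genes)),
            class = "ground_truth")
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Counts for sample j and gene g are NB with mean `L_j * p_gj`, where `L_j`
#' is the library size and `p_gj` the gene's relative intensity (baseline +
#' per-tissue effect + species log-fold change, normalized within sample) and
#' variance `mu + dispersion * mu^2`.
#'
#' @param config a [sim_config()].
#' @param truth optionally, a ground truth from [plant_effects()]; generated
#'   internally (with its own sub-seed) when omitted.
#' @return `list(counts = count_matrix, truth = ground_truth)`.
#' @export
simulate_counts <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) {
    collections <- simulate_gene_sets(config)
    truth <- plant_effects(config, collections)
  }
  genes <- gene_ids(config$n_genes)
  tissues <- sprintf("T%d", seq_len(config$n_tissues))
  set.seed(derive_seed(config$seed, "counts"))

  samples <- expand.grid(individual = seq_len(config$n_per_species),
                         species = c("human", "chimp"), tissue = tissues,
                         stringsAsFactors = FALSE)
  samples$individual <- paste0(ifelse(samples$species == "human", "h", "c"),
                               samples$individual)
  samples$sample_id <- paste(samples$tissue, samples$individual, sep = "_")
  samples <- samples[, c("sample_id", "species", "tissue", "individual")]

  b <- rnorm(config$n_genes, config$baseline_mean_log, config$baseline_sd_log)
  tau <- matrix(rnorm(config$n_genes * config$n_tissues, 0,
                      config$tissue_lfc_sd),
                config$n_genes, config$n_tissues,
                dimnames = list(genes, tissues))
  libsize <- runif(nrow(samples), config$library_size_range[1],
                   config$library_size_range[2])

  counts <- matrix(0L, config$n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    t <- samples$tissue[j]
    eta <- b + tau[, t]
    if (samples$species[j] == "chimp") eta <- eta + truth$lfc[, t]
    rel <- exp(eta)
    mu <- libsize[j] * rel / sum(rel)
    counts[, j] <- as.integer(if (config$dispersion < 1e-12) {
      rpois(config$n_genes, mu)
    } else {
      rnbinom(config$n_genes, mu = mu, size = 1 / config$dispersion)
    })
  }
  list(counts = count_matrix(counts, samples), truth = truth)
}

#' Simulate multi-study per-gene adaptation scores
#'
#' Each study scores an independent `study_coverage` fraction of genes; a
#' gene's score is its latent adaptation propensity plus a between-study
#' deviation (`heterogeneity_sd`) plus study measurement noise
#' (`study_noise_sd`).
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [plant_effects()].
#' @return list of [gene_score_table()], one per study.
#' @export
simulate_adaptation_scores <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  genes <- names(truth$adapt_propensity)
  set.seed(derive_seed(config$seed, "adapt_scores"))
  n_cov <- max(1L, round(config$study_coverage * length(genes)))
  lapply(seq_len(config$n_studies), function(i) {
    covered <- sort(sample(genes, n_cov))
    scores <- truth$adapt_propensity[covered] +
      rnorm(n_cov, 0, config$heterogeneity_sd) +
      rnorm(n_cov, 0, config$study_noise_sd)
    gene_score_table(sprintf("study%d", i), scores)
  })
}

#' Simulate a complete dataset: counts, gene sets, adaptation scores
#'
#' Orchestrates [simulate_gene_sets()], [plant_effects()],
#' [simulate_counts()] and [simulate_adaptation_scores()] under one master
#' seed. Bit-identical for identical configurations.
#'
#' @param config a [sim_config()].
#' @return a `sim_dataset` list: `config`, `counts`, `truth`, `collections`,
#'   `adapt_tables`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  collections <- simulate_gene_sets(config)
  truth <- plant_effects(config, collections)
  cnt <- simulate_counts(config, truth)
  adapt <- simulate_adaptation_scores(config, truth)
  structure(list(config = config, counts = cnt$counts, truth = truth,
                 collections = collections, adapt_tables = adapt),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits the counts and sample-metadata TSVs, one GMT per collection, one
#' score TSV per study, and a ground-truth JSON.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_counts(dataset$counts,
                        file.path(outdir, "counts.tsv"),
                        file.path(outdir, "samples.tsv"))
  for (coll in dataset$collections)
    paths <- c(paths, write_gmt(coll, file.path(
      outdir, paste0(coll$collection_id, ".gmt"))))
  for (tab in dataset$adapt_tables) {
    p <- file.path(outdir, paste0(tab$study_id, "_scores.tsv"))
    write_scores(tab, p)
    paths <- c(paths, p)
  }
  truth <- dataset$truth
  gt <- list(de_genes = truth$de_genes,
             coupled_collections = truth$coupled_collections,
             tissue_confined = as.list(truth$tissue_confined[
               !is.na(truth$tissue_confined)]),
             set_effects = truth$set_effects,
             adapt_propensity = as.list(truth$adapt_propensity),
             lfc = apply(truth$lfc, 1, as.list, simplify = FALSE))
  gt_path <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, gt_path))
}
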