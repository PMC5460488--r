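#' Construct a validated count matrix with sample metadata
#'
#' The expression input of the pipeline: a gene x sample matrix of raw
#' nonnegative integer counts plus per-sample species, tissue and individual
#' labels.
#'
#' @param counts gene x sample matrix of nonnegative integers with unique
#'   row (gene) and column (sample) names.
#' @param samples data frame with columns `sample_id`, `species`, `tissue`,
#'   `individual`, one row per column of `counts`, in the same order.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("count matrix needs unique gene (row) names", call. = FALSE)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("count matrix needs unique sample (column) names", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be finite nonnegative integers", call. = FALSE)
  req <- c("sample_id", "species", "tissue", "individual")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stop("'samples' must have columns sample_id, species, tissue, individual",
         call. = FALSE)
  samples <- as.data.frame(samples)[, req]
  if (!identical(as.character(samples$sample_id), colnames(counts)))
    stop("sample metadata does not match count matrix columns: ",
         paste(setdiff(union(samples$sample_id, colnames(counts)),
                       intersect(samples$sample_id, colnames(counts))),
               collapse = ", "), call. = FALSE)
  for (col in req) {
    if (any(is.na(samples[[col]])) || any(!nzchar(as.character(samples[[col]]))))
      stop("sample metadata column '", col, "' has missing labels", call. = FALSE)
  }
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d tissues, %d species)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$tissue)),
              length(unique(x$samples$species))))
  invisible(x)
}

#' Construct a per-gene score table
#'
#' Holds one study's per-gene ordinal scores (a differential-expression score
#' or an adaptation score; higher means stronger signal), optionally with
#' standard errors.
#'
#' @param study_id label for the study the scores come from.
#' @param scores named numeric vector, one finite score per unique gene.
#' @param se optional named numeric vector of nonnegative standard errors.
#' @return an object of class `gene_score_table`.
#' @export
gene_score_table <- function(study_id, scores, se = NULL) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be named with unique gene ids", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  if (!is.null(se)) {
    if (!identical(names(se), names(scores)) || any(!is.finite(se)) || any(se < 0))
      stop("'se' must align with scores and be finite and >= 0", call. = FALSE)
  }
  structure(list(study_id = as.character(study_id), scores = scores, se = se),
            class = "gene_score_table")
}

#' Construct a gene-set collection
#'
#' @param collection_id label for the collection.
#' @param sets named list; each element is `list(description =, genes =)` with
#'   a non-empty character vector of unique gene ids.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(collection_id, sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be unique", call. = FALSE)
  for (nm in names(sets)) {
    g <- sets[[nm]]$genes
    if (length(g) == 0)
      stop("set '", nm, "' is empty", call. = FALSE)
    if (anyDuplicated(g) || any(!nzchar(g)))
      stop("set '", nm, "' has duplicate or empty gene ids", call. = FALSE)
  }
  structure(list(collection_id = as.character(collection_id), sets = sets),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets, sizes %s\n",
              x$collection_id, length(x$sets),
              paste(range(vapply(x$sets, function(s) length(s$genes), 1L)),
                    collapse = "-")))
  invisible(x)
}

# GMT ---------------------------------------------------------------------

#' Read a gene-set collection from a GMT file
#'
#' GMT is the MSigDB exchange format: one set per line, tab-separated as
#' set name, description, then one or more member genes.
#'
#' @param path path to a GMT file.
#' @param collection_id collection label; defaults to the file name without
#'   extension.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, collection_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(collection_id))
    collection_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("%s line %d: GMT lines need name, description and >= 1 gene",
                   path, i), call. = FALSE)
    nm <- fields[1]
    if (nm %in% names(sets))
      stop(sprintf("%s line %d: duplicate set name '%s'", path, i, nm),
           call. = FALSE)
    sets[[nm]] <- list(description = fields[2], genes = fields[-(1:2)])
  }
  gene_set_collection(collection_id, sets)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# TSV tables ---------------------------------------------------------------

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' The counts file has a `gene` column then one integer column per sample;
#' the metadata file has columns `sample_id`, `species`, `tissue`,
#' `individual`. Lines starting with `#` are ignored.
#'
#' @param counts_path,meta_path paths to the two TSV files.
#' @return a [count_matrix()].
#' @export
read_counts <- function(counts_path, meta_path) {
  tab <- read_tsv_table(counts_path)
  if (names(tab)[1] != "gene")
    stop("first column of the counts file must be 'gene'", call. = FALSE)
  meta <- read_tsv_table(meta_path)
  genes <- as.character(tab$gene)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count for gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(mat)[bad[1, 2]]), call. = FALSE)
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  count_matrix(mat, meta)
}

#' Write a count matrix and its metadata as TSV files
#'
#' @param cm a [count_matrix()].
#' @param counts_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(cm, counts_path, meta_path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(gene = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, meta_path))
}

#' Read a per-gene score table from TSV
#'
#' Expects a header with columns `gene` and `score` (and optionally `se`).
#'
#' @param path path to the TSV file.
#' @param study_id study label to attach.
#' @return a [gene_score_table()].
#' @export
read_scores <- function(path, study_id) {
  tab <- read_tsv_table(path)
  if (!all(c("gene", "score") %in% names(tab)))
    stop("score table needs 'gene' and 'score' columns", call. = FALSE)
  if (anyDuplicated(tab$gene))
    stop("duplicate gene rows in ", path, call. = FALSE)
  score_num <- suppressWarnings(as.numeric(tab$score))
  if (any(is.na(score_num)))
    stop("non-numeric score for gene '", tab$gene[which(is.na(score_num))[1]],
         "'", call. = FALSE)
  se <- NULL
  if ("se" %in% names(tab))
    se <- setNames(as.numeric(tab$se), as.character(tab$gene))
  gene_score_table(study_id, setNames(score_num, as.character(tab$gene)), se)
}

#' Write a per-gene score table as TSV
#'
#' @param table a [gene_score_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  stopifnot(inherits(table, "gene_score_table"))
  tab <- data.frame(gene = names(table$scores),
                    score = signif(table$scores, 6),
                    stringsAsFactors = FALSE)
  if (!is.null(table$se)) tab$se <- signif(table$se, 6)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables as TSV files with fixed precision
#'
#' Serializes a named list of result data frames (enrichment, meta-analysis,
#' functional-correlation tables) into `outdir`, one `<name>.tsv` each, with
#' numeric columns at 6 significant digits and a deterministic column order.
#'
#' @param tables named list of data frames.
#' @param outdir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, outdir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    path <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
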