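# Readers and writers for the plain-text formats the pipeline exchanges:
# expression TSV (genes x samples), covariates TSV, gene annotation TSV,
# BED-like motif hit TSV, PPI edge-list TSV, sparse prior edge-list TSV,
# GMT gene sets, drug library TSV, truth record JSON.

#' Read / write a gene x sample expression matrix as TSV
#'
#' Tab-separated with a `gene_id` first column and one column per sample.
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param x Matrix to write.
#' @export
write_expression_tsv <- function(x, path) {
  d <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample covariates as TSV
#' @param path File path.
#' @return data.frame with one row per sample.
#' @export
read_covariates_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_covariates_tsv
#' @param covariates data.frame to write.
#' @export
write_covariates_tsv <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene annotations (gene_id, chromosome, strand, tss) as TSV
#' @param path File path.
#' @export
read_annotations_tsv <- function(path) {
  check_annotations(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_annotations_tsv
#' @param annotations data.frame to write.
#' @export
write_annotations_tsv <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BED-like motif hits (chromosome, start, end, tf_id, p_value)
#'
#' Columns may appear in any order if a header is present; a headerless
#' 5-column file is read positionally in BED-like order.
#' @param path File path.
#' @return data.frame with columns `tf_id`, `chromosome`, `start`, `end`,
#'   `p_value`.
#' @export
read_motif_hits <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("tf_id", first)) {
    d <- read.delim(path, stringsAsFactors = FALSE)
  } else {
    d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(d) <- c("chromosome", "start", "end", "tf_id", "p_value")
  }
  d[, c("tf_id", "chromosome", "start", "end", "p_value")]
}

#' @rdname read_motif_hits
#' @param hits data.frame of hits to write (BED-like column order, header).
#' @export
write_motif_hits <- function(hits, path) {
  write.table(hits[, c("chromosome", "start", "end", "tf_id", "p_value")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a TF-TF interaction edge list (tf_a, tf_b, score 0-1000)
#' @param path File path.
#' @export
read_ppi_edges <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_ppi_edges
#' @param ppi A `ppi_prior` to write (scores rescaled to 0-1000, upper
#'   triangle only, diagonal omitted).
#' @export
write_ppi_edges <- function(ppi, path) {
  s <- ppi$scores
  idx <- which(upper.tri(s) & s != 0, arr.ind = TRUE)
  d <- data.frame(tf_a = ppi$tfs[idx[, 1]], tf_b = ppi$tfs[idx[, 2]],
                  score = s[idx] * 1000)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a motif prior as a sparse edge list (tf, gene, weight)
#' @param prior A `motif_prior`.
#' @param path File path.
#' @export
write_prior_edges <- function(prior, path) {
  idx <- which(prior$edges != 0, arr.ind = TRUE)
  d <- data.frame(tf = prior$tfs[idx[, 1]], gene = prior$genes[idx[, 2]],
                  weight = prior$edges[idx])
  d <- d[order(d$tf, d$gene), ]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prior_edges
#' @param tfs,genes Full orderings (edge lists are sparse).
#' @export
read_prior_edges <- function(path, tfs, genes) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  edges <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  edges[cbind(match(d$tf, tfs), match(d$gene, genes))] <- d$weight
  structure(list(tfs = tfs, genes = genes, edges = edges), class = "motif_prior")
}

#' Read / write gene set collections in GMT format
#'
#' Tab-separated: set name, description, then gene ids.
#' @param path File path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  stopifnot(!anyDuplicated(names(sets)), all(lengths(sets) > 0))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a drug signature library as long TSV (drug, direction, gene)
#' @param path File path.
#' @export
read_drug_library <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(d, d$drug), function(dd)
    structure(list(id = dd$drug[1],
                   up = dd$gene[dd$direction == "up"],
                   down = dd$gene[dd$direction == "down"]),
              class = "drug_signature"))
}

#' @rdname read_drug_library
#' @param library Named list of `drug_signature`s.
#' @export
write_drug_library <- function(library, path) {
  d <- do.call(rbind, lapply(library, function(sig)
    data.frame(drug = sig$id,
               direction = rep(c("up", "down"), c(length(sig$up), length(sig$down))),
               gene = c(sig$up, sig$down))))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every component of a synthetic cohort to a directory
#'
#' Emits the formats the pipeline reads: expression TSV, covariates TSV,
#' annotation TSV, motif prior edge list, PPI edge list, GMT gene sets, drug
#' library TSV and the truth record as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv")),
    covariates = write_covariates_tsv(cohort$covariates, file.path(dir, "covariates.tsv")),
    annotations = write_annotations_tsv(cohort$annotations, file.path(dir, "annotations.tsv")),
    motif_prior = write_prior_edges(cohort$motif_prior, file.path(dir, "motif_prior.tsv")),
    ppi = write_ppi_edges(cohort$ppi_prior, file.path(dir, "ppi.tsv")),
    gene_sets = write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt")),
    drug_library = write_drug_library(cohort$drug_library, file.path(dir, "drug_library.tsv")))
  truth_path <- file.path(dir, "truth.json")
  truth <- cohort$truth
  truth$pathway_activity <- NULL  # large; regenerate from the spec seed
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  c(paths, truth = truth_path)
}
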