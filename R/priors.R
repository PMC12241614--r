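#' Build a TF-to-gene motif prior from motif hits and gene annotations
#'
#' A prior regulatory network is a bipartite binary matrix marking, for every
#' transcription factor (TF), whether one of its significant motif hits falls
#' inside a gene's promoter window. The promoter window is defined relative to
#' the transcription direction: for a `+` strand gene with transcription start
#' site (TSS) `t` the window is `[t - upstream, t + downstream]`; for a `-`
#' strand gene it is mirrored to `[t - downstream, t + upstream]`. Coordinates
#' are 1-based inclusive and overlap means at least one shared base.
#'
#' @param hits data.frame with columns `tf_id`, `chromosome`, `start`, `end`,
#'   `p_value` (1-based inclusive intervals).
#' @param annotations data.frame with columns `gene_id`, `chromosome`,
#'   `strand` (`"+"`/`"-"`), `tss`.
#' @param upstream,downstream Window extent in bases (default 750 upstream,
#'   250 downstream of the TSS).
#' @param p_threshold Hits with `p_value < p_threshold` are retained
#'   (default `1e-5`, strict inequality).
#' @param tfs Optional TF ordering; defaults to sorted TFs seen in `hits`.
#' @return A `motif_prior`: list with `tfs`, `genes` and a binary TF x gene
#'   `edges` matrix; attribute `n_ignored_hits` counts hits on chromosomes
#'   absent from the annotation.
#' @export
build_motif_prior <- function(hits, annotations, upstream = 750,
                              downstream = 250, p_threshold = 1e-5,
                              tfs = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  check_annotations(annotations)
  stopifnot(all(c("tf_id", "chromosome", "start", "end", "p_value") %in% names(hits)))
  if (nrow(hits) > 0) {
    stopifnot(all(hits$start <= hits$end), all(hits$p_value > 0), all(hits$p_value <= 1))
  }
  genes <- annotations$gene_id
  tfs <- tfs %||% sort(unique(hits$tf_id))
  edges <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))

  n_ignored <- 0L
  if (nrow(hits) > 0) {
    hits <- hits[hits$p_value < p_threshold, , drop = FALSE]
    bad <- !(hits$chromosome %in% annotations$chromosome)
    n_ignored <- sum(bad)
    if (n_ignored > 0) {
      warning(sprintf("%d motif hits on chromosomes absent from the annotation were ignored", n_ignored))
      hits <- hits[!bad, , drop = FALSE]
    }
    win_lo <- ifelse(annotations$strand == "+",
                     annotations$tss - upstream, annotations$tss - downstream)
    win_hi <- ifelse(annotations$strand == "+",
                     annotations$tss + downstream, annotations$tss + upstream)
    for (k in seq_len(nrow(hits))) {
      g <- which(annotations$chromosome == hits$chromosome[k] &
                   win_lo <= hits$end[k] & win_hi >= hits$start[k])
      if (length(g)) edges[hits$tf_id[k], g] <- 1
    }
  }
  structure(list(tfs = tfs, genes = genes, edges = edges),
            class = "motif_prior", n_ignored_hits = n_ignored)
}

#' Make a motif prior sex-specific
#'
#' Female samples lack a Y chromosome, so in the female prior every edge into
#' a chrY gene is downweighed to zero; the male prior is the input unchanged.
#' Zeroing only ever removes edges.
#'
#' @param prior A `motif_prior`.
#' @param sex `"female"` or `"male"`.
#' @param annotations Gene annotation data.frame covering all prior genes.
#' @return A `motif_prior`.
#' @export
make_sex_specific_prior <- function(prior, sex = c("female", "male"), annotations) {
  sex <- match.arg(sex)
  check_annotations(annotations)
  stopifnot(all(prior$genes %in% annotations$gene_id))
  if (sex == "male") return(prior)
  chry <- annotations$gene_id[annotations$chromosome %in% c("chrY", "Y")]
  prior$edges[, prior$genes %in% chry] <- 0
  prior
}

#' Build a symmetric TF-TF interaction prior from scored interactions
#'
#' Interaction scores on the 0-1000 scale (STRING-style) are normalized by
#' dividing by 1000; the matrix is symmetrized (taking the maximum when both
#' directions are given), self-interactions are set to one for every TF, and
#' missing pairs are zero.
#'
#' @param interactions data.frame with columns `tf_a`, `tf_b`, `score`
#'   (scores in `[0, 1000]`); may have zero rows.
#' @param tfs Ordered TF id list.
#' @return A `ppi_prior`: list with `tfs` and a symmetric TF x TF `scores`
#'   matrix in `[0, 1]` with unit diagonal.
#' @export
build_ppi_prior <- function(interactions, tfs) {
  stopifnot(length(tfs) > 0, !anyDuplicated(tfs))
  scores <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  if (nrow(interactions) > 0) {
    stopifnot(all(c("tf_a", "tf_b", "score") %in% names(interactions)))
    if (any(interactions$score < 0 | interactions$score > 1000))
      stop("interaction scores must lie in [0, 1000]")
    keep <- interactions$tf_a %in% tfs & interactions$tf_b %in% tfs
    interactions <- interactions[keep, , drop = FALSE]
    for (k in seq_len(nrow(interactions))) {
      a <- interactions$tf_a[k]; b <- interactions$tf_b[k]
      s <- interactions$score[k] / 1000
      scores[a, b] <- max(scores[a, b], s)
      scores[b, a] <- scores[a, b]
    }
  }
  diag(scores) <- 1
  structure(list(tfs = tfs, scores = scores), class = "ppi_prior")
}

#' Filter an expression matrix for network inference
#'
#' Drops lowly expressed genes (a gene is removed iff its value falls below
#' `tpm_threshold` in at least `sample_fraction` of the samples), intersects
#' the survivors with the prior gene set, and replaces chrY values of female
#' samples by `NA`. Gene order is preserved.
#'
#' @param raw Gene x sample numeric matrix (TPM-like, nonnegative), with
#'   rownames = gene ids and colnames = sample ids.
#' @param covariates data.frame with `sample_id` and `sex` columns covering
#'   all samples.
#' @param tpm_threshold,sample_fraction Filter parameters (defaults 1 TPM and
#'   0.10 of samples).
#' @param prior_genes Gene ids present in the motif prior.
#' @param annotations Gene annotation data.frame (for chrY membership).
#' @return Filtered gene x sample matrix.
#' @export
preprocess_expression <- function(raw, covariates, tpm_threshold = 1,
                                  sample_fraction = 0.10, prior_genes,
                                  annotations) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)), !is.null(colnames(raw)))
  stopifnot(all(colnames(raw) %in% covariates$sample_id))
  n <- ncol(raw)
  low <- rowSums(raw < tpm_threshold, na.rm = TRUE)
  keep <- low < sample_fraction * n          # dropped iff count >= fraction * n
  out <- raw[keep & rownames(raw) %in% prior_genes, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no genes survive filtering and intersection with the prior gene set")
  chry <- annotations$gene_id[annotations$chromosome %in% c("chrY", "Y")]
  sex <- covariates$sex[match(colnames(out), covariates$sample_id)]
  if (length(chry) && any(sex == "female"))
    out[rownames(out) %in% chry, sex == "female"] <- NA_real_
  out
}

check_annotations <- function(annotations) {
  stopifnot(all(c("gene_id", "chromosome", "strand", "tss") %in% names(annotations)))
  stopifnot(!anyDuplicated(annotations$gene_id),
            all(annotations$strand %in% c("+", "-")),
            all(annotations$tss >= 1))
  invisible(annotations)
}

#' @export
print.motif_prior <- function(x, ...) {
  cat(sprintf("motif prior: %d TFs x %d genes, %d edges\n",
              length(x$tfs), length(x$genes), sum(x$edges != 0)))
  invisible(x)
}

#' @export
print.ppi_prior <- function(x, ...) {
  off <- x$scores; diag(off) <- 0
  cat(sprintf("PPI prior: %d TFs, %d scored pairs\n",
              length(x$tfs), sum(off != 0) / 2))
  invisible(x)
}
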