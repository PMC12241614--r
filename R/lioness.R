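# Fast leave-one-out Pearson correlation via downdated sufficient statistics.
# Rows of `expr` that are entirely NA (chrY genes in a female stratum) are
# zero-filled; scattered NAs fall back to the pairwise-complete path.
loo_coexpression_fn <- function(expr) {
  g <- nrow(expr)
  gnames <- rownames(expr)
  na_counts <- rowSums(is.na(expr))
  scattered <- any(!(na_counts %in% c(0L, ncol(expr))))
  if (scattered) {
    return(function(drop_idx = NULL) {
      e <- if (is.null(drop_idx)) expr else expr[, -drop_idx, drop = FALSE]
      coexpression(e)
    })
  }
  comp <- na_counts == 0L
  X <- t(expr[comp, , drop = FALSE])      # samples x complete genes
  S <- colSums(X)
  Q <- crossprod(X)
  n <- nrow(X)
  function(drop_idx = NULL) {
    if (is.null(drop_idx)) {
      n2 <- n; S2 <- S; Q2 <- Q
    } else {
      xq <- X[drop_idx, ]
      n2 <- n - 1L
      S2 <- S - xq
      Q2 <- Q - tcrossprod(xq)
    }
    covm <- Q2 / n2 - tcrossprod(S2 / n2)
    sdv <- sqrt(diag(covm))
    cc <- covm / tcrossprod(sdv)
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    C <- matrix(0, g, g, dimnames = list(gnames, gnames))
    C[comp, comp] <- cc
    diag(C) <- 1
    C
  }
}

#' Single-sample network estimation by linear interpolation
#'
#' Estimates one regulatory network per sample from an aggregate network
#' function: for sample `q` out of `N`,
#' `e(q) = N * (e(all) - e(all minus q)) + e(all minus q)`,
#' where `e(.)` is the network computed on the indicated sample subset. The
#' default network function is message-passing inference ([panda()]) on the
#' subset's coexpression matrix, with the leave-one-out correlation obtained
#' by downdating cached sufficient statistics.
#'
#' @param expr Gene x sample expression matrix (>= 4 samples).
#' @param motif,ppi Priors as in [panda()] (ignored when `network_fn` given).
#' @param network_fn Optional function of an expression submatrix returning a
#'   numeric network (matrix or vector); overrides the default.
#' @param ... Configuration passed to [panda()] (`alpha`, `tolerance`, ...).
#' @return A `lioness` object: `networks` (named list, one per sample),
#'   `aggregate`, `tfs`, `genes`, `samples` and provenance.
#' @export
lioness <- function(expr, motif = NULL, ppi = NULL, network_fn = NULL, ...) {
  stopifnot(is.matrix(expr))
  N <- ncol(expr)
  if (N < 4) stop("single-sample estimation requires at least 4 samples")
  samples <- colnames(expr) %||% paste0("s", seq_len(N))

  agg <- NULL
  if (is.null(network_fn)) {
    stopifnot(!is.null(motif), !is.null(ppi))
    cfn <- loo_coexpression_fn(expr)
    network_fn_int <- function(drop_idx) {
      fit <- panda(motif, ppi, cfn(drop_idx), ...)
      fit$weights
    }
    e_all <- network_fn_int(NULL)
    nets <- vector("list", N)
    for (q in seq_len(N)) {
      e_mq <- network_fn_int(q)
      nets[[q]] <- N * (e_all - e_mq) + e_mq
    }
    agg <- panda(motif, ppi, cfn(NULL), ...)
  } else {
    e_all <- network_fn(expr)
    nets <- vector("list", N)
    for (q in seq_len(N)) {
      e_mq <- network_fn(expr[, -q, drop = FALSE])
      nets[[q]] <- N * (e_all - e_mq) + e_mq
    }
  }
  names(nets) <- samples
  tfs <- if (is.matrix(e_all)) rownames(e_all) else NULL
  genes <- if (is.matrix(e_all)) colnames(e_all) else names(e_all)
  structure(list(networks = nets, aggregate = agg %||% e_all, tfs = tfs,
                 genes = genes, samples = samples,
                 config = list(...)),
            class = "lioness")
}

#' @export
print.lioness <- function(x, ...) {
  cat(sprintf("single-sample networks: %d samples", length(x$networks)))
  if (!is.null(x$tfs))
    cat(sprintf(", %d TFs x %d genes each", length(x$tfs), length(x$genes)))
  cat("\n")
  invisible(x)
}

#' Gene targeting scores (indegrees)
#'
#' The targeting score of a gene in one sample's network is the sum of all
#' incoming edge weights from all TFs. Indegree is linear in the weights.
#'
#' @param networks A `lioness` object, a list of TF x gene matrices, or a
#'   single TF x gene matrix / `panda` object.
#' @return Gene x sample matrix (or a named vector for a single network).
#' @export
indegree <- function(networks) {
  if (inherits(networks, "panda")) return(colSums(networks$weights))
  if (is.matrix(networks)) return(colSums(networks))
  nets <- if (inherits(networks, "lioness")) networks$networks else networks
  stopifnot(length(nets) > 0)
  out <- vapply(nets, function(w) if (is.matrix(w)) colSums(w) else as.numeric(w),
                numeric(if (is.matrix(nets[[1]])) ncol(nets[[1]]) else length(nets[[1]])))
  if (is.matrix(nets[[1]])) rownames(out) <- colnames(nets[[1]])
  out
}

#' Sex-stratified single-sample network inference
#'
#' Runs [lioness()] separately for female and male samples — the female
#' stratum with the female-specific motif prior (chrY edges zeroed) — and
#' merges the per-sample targeting scores back into the original sample
#' order. Gene orderings are asserted identical across strata.
#'
#' @param expr Gene x sample expression matrix.
#' @param motif,ppi Priors.
#' @param covariates data.frame with `sample_id` and `sex`.
#' @param annotations Gene annotations (for chrY membership).
#' @param stratify_by_sex Stratify (default) or run all samples together.
#' @param keep_networks Keep per-sample weight matrices (memory-heavy).
#' @param ... Passed to [panda()].
#' @return List with `indegree` (gene x sample matrix, original sample
#'   order), `strata`, and optionally `networks`.
#' @export
infer_sample_networks <- function(expr, motif, ppi, covariates, annotations,
                                  stratify_by_sex = TRUE, keep_networks = FALSE,
                                  ...) {
  stopifnot(all(colnames(expr) %in% covariates$sample_id))
  sex <- covariates$sex[match(colnames(expr), covariates$sample_id)]
  strata <- if (stratify_by_sex) split(seq_len(ncol(expr)), sex) else
    list(all = seq_len(ncol(expr)))
  scores <- matrix(NA_real_, length(motif$genes), ncol(expr),
                   dimnames = list(motif$genes, colnames(expr)))
  nets <- list()
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    pr <- if (stratify_by_sex && nm == "female")
      make_sex_specific_prior(motif, "female", annotations) else motif
    fit <- lioness(expr[, idx, drop = FALSE], pr, ppi, ...)
    stopifnot(identical(fit$genes, motif$genes))
    scores[, idx] <- indegree(fit)
    if (keep_networks) nets[[nm]] <- fit
  }
  out <- list(indegree = scores, strata = lapply(strata, function(i) colnames(expr)[i]))
  if (keep_networks) out$networks <- nets
  out
}
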