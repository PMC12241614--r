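#' Row/column z-score normalization for network inference inputs
#'
#' Each entry is replaced by the average of its row z-score and its column
#' z-score, scaled by `1/sqrt(2)`. Standard deviations are population SDs
#' (denominator `n`). Any row or column with zero SD falls back to the
#' overall-matrix z-score for its term; an all-constant matrix maps to all
#' zeros. The output is invariant under adding a constant to the input.
#'
#' @param x Numeric matrix with at least 2 rows and 2 columns.
#' @return Normalized matrix of the same shape.
#' @export
zscore_normalize <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) >= 2, all(is.finite(x)))
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  rmu <- rowMeans(x)
  rsd <- sqrt(rowMeans((x - rmu)^2))
  cmu <- colMeans(x)
  csd <- sqrt(colMeans(sweep(x, 2, cmu)^2))
  if (s == 0) return(array(0, dim(x), dimnames = dimnames(x)))
  zr <- (x - rmu) / rsd
  zc <- sweep(sweep(x, 2, cmu), 2, csd, "/")
  if (any(rsd == 0)) zr[rsd == 0, ] <- (x[rsd == 0, , drop = FALSE] - mu) / s
  if (any(csd == 0)) zc[, csd == 0] <- (x[, csd == 0, drop = FALSE] - mu) / s
  (zr + zc) / sqrt(2)
}

#' Continuous Tanimoto similarity between row vectors of X and column vectors of Y
#'
#' `T(i, j) = a / sqrt(||X_i||^2 + ||Y_j||^2 - |a|)` with `a = X_i . Y_j`.
#' When both vectors are zero the similarity is 0 by convention.
#'
#' @param x n x k numeric matrix.
#' @param y k x m numeric matrix.
#' @return n x m similarity matrix.
#' @export
tanimoto <- function(x, y) {
  stopifnot(ncol(x) == nrow(y))
  a <- x %*% y
  den <- sqrt(outer(rowSums(x^2), colSums(y^2), "+") - abs(a))
  r <- a / den
  r[!is.finite(r)] <- 0
  r
}

#' Gene-gene coexpression matrix
#'
#' Pearson correlation between gene rows; missing values are handled
#' pairwise-complete, the diagonal is 1, and zero-variance (or all-missing)
#' genes get 0 off-diagonal. Genes whose rows are entirely missing (e.g. chrY
#' genes in a female stratum) are dropped from the fast complete-data path
#' and zero-filled.
#'
#' @param expr Gene x sample numeric matrix (>= 3 samples).
#' @return Gene x gene correlation matrix.
#' @export
coexpression <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3) stop("coexpression requires at least 3 samples")
  x <- t(expr)
  if (anyNA(x)) {
    all_na <- colSums(!is.na(x)) == 0
    if (all(colSums(is.na(x)) %in% c(0L, nrow(x)))) {
      # complete rows + fully-missing rows: fast path on the complete block
      C <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
      cc <- suppressWarnings(cor(x[, !all_na, drop = FALSE]))
      C[!all_na, !all_na] <- cc
    } else {
      C <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
    }
  } else {
    C <- suppressWarnings(cor(x))
  }
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

#' Aggregate network inference by message passing
#'
#' Refines a binary motif prior into a continuous TF x gene regulatory
#' network by iteratively reconciling three evidence channels: the prior
#' itself, TF-TF cooperativity (PPI) and gene-gene coexpression. Each
#' iteration computes a responsibility (agreement of the PPI channel with the
#' current network) and an availability (agreement of the network with the
#' coexpression channel) through a continuous Tanimoto kernel, and moves the
#' network a step of size `alpha` toward their mean; the PPI and coexpression
#' channels are in turn moved toward the network's self-similarity, with a
#' diagonal refresh. Iteration stops when the mean absolute edge change drops
#' below `tolerance`.
#'
#' @param motif A `motif_prior` or TF x gene matrix.
#' @param ppi A `ppi_prior` or TF x TF matrix.
#' @param coexpr Gene x gene coexpression matrix (e.g. [coexpression()]), or
#'   a gene x sample expression matrix if `from_expression = TRUE`.
#' @param alpha Learning rate in (0, 1]; default 0.1.
#' @param tolerance Convergence threshold on mean |delta W|; default 0.001.
#' @param max_iterations Iteration cap; default 200.
#' @param strict_reference_mode If `TRUE` (default) the diagonal refresh of
#'   the self-similarity updates follows the reference convention
#'   (off-diagonal row SD scaled by dimension and `exp(2 * alpha * step)`);
#'   if `FALSE` a simplified refresh to the off-diagonal row SD is used.
#' @param from_expression Treat `coexpr` as expression and correlate it first.
#' @return A `panda` object: `weights` (TF x gene z-like scores, may be
#'   negative), `tfs`, `genes`, `iterations_run`, `converged`, `delta_trace`
#'   and the configuration.
#' @export
panda <- function(motif, ppi, coexpr, alpha = 0.1, tolerance = 0.001,
                  max_iterations = 200, strict_reference_mode = TRUE,
                  from_expression = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, tolerance > 0, max_iterations >= 1)
  if (inherits(motif, "motif_prior")) {
    tfs <- motif$tfs; genes <- motif$genes; M <- motif$edges
  } else {
    M <- motif
    tfs <- rownames(M) %||% paste0("tf", seq_len(nrow(M)))
    genes <- colnames(M) %||% paste0("g", seq_len(ncol(M)))
  }
  P <- if (inherits(ppi, "ppi_prior")) ppi$scores else ppi
  if (from_expression) coexpr <- coexpression(coexpr)
  stopifnot(nrow(P) == nrow(M), ncol(P) == nrow(M),
            nrow(coexpr) == ncol(M), ncol(coexpr) == ncol(M))
  if (!is.null(rownames(coexpr)) && !is.null(colnames(M)))
    stopifnot(identical(rownames(coexpr), colnames(M)))

  W0 <- zscore_normalize(M)
  res <- panda_core(W0, zscore_normalize(P), zscore_normalize(coexpr),
                    alpha, tolerance, as.integer(max_iterations),
                    isTRUE(strict_reference_mode))
  W <- res$weights
  dimnames(W) <- list(tfs, genes)
  structure(list(weights = W, tfs = tfs, genes = genes,
                 iterations_run = res$iterations_run,
                 converged = res$converged,
                 delta_trace = res$delta_trace,
                 config = list(alpha = alpha, tolerance = tolerance,
                               max_iterations = max_iterations,
                               strict_reference_mode = strict_reference_mode)),
            class = "panda")
}

#' @export
print.panda <- function(x, ...) {
  cat(sprintf("aggregate regulatory network: %d TFs x %d genes\n",
              length(x$tfs), length(x$genes)))
  cat(sprintf("  %d iterations, %sconverged (final mean |dW| = %.3g)\n",
              x$iterations_run, if (x$converged) "" else "NOT ",
              x$delta_trace[length(x$delta_trace)]))
  invisible(x)
}
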