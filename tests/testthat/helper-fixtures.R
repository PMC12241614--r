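# Shared toy fixtures, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

toy_annotations <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gY1", "gY2"),
    chromosome = c("chr1", "chr1", "chr2", "chr2", "chrY", "chrY"),
    strand = c("+", "-", "+", "-", "+", "+"),
    tss = c(10000L, 20000L, 5000L, 8000L, 3000L, 7000L))
}

toy_motif_prior <- function() {
  edges <- rbind(tf1 = c(1, 0, 1, 0, 1, 0),
                 tf2 = c(0, 1, 0, 1, 0, 1),
                 tf3 = c(1, 1, 0, 0, 1, 1))
  colnames(edges) <- c("gA", "gB", "gC", "gD", "gY1", "gY2")
  structure(list(tfs = rownames(edges), genes = colnames(edges),
                 edges = edges), class = "motif_prior")
}

# small dense random expression with named dims
toy_expression <- function(n_genes = 6, n_samples = 8, seed = 42) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_samples, mean = 5)), n_genes, n_samples)
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n_samples)))
  m
}

# independent transcription of the message-passing update equations, used as
# the single-step oracle; deliberately written without the package's C++ core
panda_single_step_oracle <- function(motif, ppi, coexpr, alpha) {
  zs <- function(x) {
    mu <- mean(x); s <- sqrt(mean((x - mu)^2))
    rmu <- rowMeans(x); rsd <- sqrt(rowMeans((x - rmu)^2))
    cmu <- colMeans(x); csd <- sqrt(colMeans(sweep(x, 2, cmu)^2))
    zr <- (x - rmu) / rsd
    zc <- sweep(sweep(x, 2, cmu), 2, csd, "/")
    if (any(rsd == 0)) zr[rsd == 0, ] <- (x[rsd == 0, , drop = FALSE] - mu) / s
    if (any(csd == 0)) zc[, csd == 0] <- (x[, csd == 0, drop = FALSE] - mu) / s
    (zr + zc) / sqrt(2)
  }
  tf <- function(X, Y) {
    a <- X %*% Y
    den <- sqrt(outer(rowSums(X^2), colSums(Y^2), "+") - abs(a))
    out <- a / den; out[!is.finite(out)] <- 0; out
  }
  W <- zs(motif); P <- zs(ppi); C <- zs(coexpr)
  R <- tf(P, W)
  A <- tf(W, C)
  (1 - alpha) * W + alpha * 0.5 * (R + A)
}

# rank-based AUC of `stat` for separating TRUE labels from FALSE
rank_auc <- function(stat, label) {
  r <- rank(stat)
  (mean(r[label]) - (sum(label) + 1) / 2) / sum(!label)
}
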