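# Reference levels give coefficients a fixed, documented meaning: never-smoker,
# female, healthy, white, stage I.
covariate_factors <- function(covariates) {
  cf <- covariates
  if ("sex" %in% names(cf)) cf$sex <- factor(cf$sex, c("female", "male"))
  if ("smoking" %in% names(cf)) cf$smoking <- factor(cf$smoking, c("never", "ever"))
  if ("disease" %in% names(cf))
    cf$disease <- factor(cf$disease, c("healthy", "tumor", "normal_adjacent"))
  if ("race" %in% names(cf))
    cf$race <- factor(cf$race, unique(c("white", sort(unique(cf$race[!is.na(cf$race)])))))
  if ("stage" %in% names(cf))
    cf$stage <- factor(cf$stage, unique(c("I", sort(unique(cf$stage[!is.na(cf$stage)])))))
  cf
}

#' Differential TF-targeting analysis
#'
#' Fits, for every gene, a covariate-adjusted linear model of its targeting
#' score (indegree) and extracts the coefficient of interest: the age slope
#' (`model = "age"`, the change in indegree per year of age), the
#' tumor-versus-healthy contrast (`model = "disease"`), or the age-by-smoking
#' interaction (`model = "interaction"`). Per-gene models share one design
#' matrix; genes with missing responses are fitted on their complete cases.
#' Empirical-Bayes variance moderation (the limma scheme) yields moderated
#' t-statistics alongside the ordinary ones.
#'
#' @param scores Gene x sample targeting-score matrix ([indegree()]).
#' @param covariates data.frame with `sample_id`, `age`, `sex`, `smoking`,
#'   and optionally `race`, `disease`, `stage`, `rin`, `batch`,
#'   `ischemic_time`.
#' @param model Coefficient of interest (see above).
#' @param adjust Adjustment covariate names; defaults per model to those
#'   available with more than one observed level.
#' @param moderated Use moderated p-values in `t`/`p`/`fdr` (default) or the
#'   ordinary ones.
#' @return A `diff_targeting` data.frame with per-gene `slope`, `t_ordinary`,
#'   `p_ordinary`, `t_moderated`, `p_moderated`, `t`, `p`, `fdr`,
#'   `df_residual`, `sigma2`.
#' @export
diff_targeting <- function(scores, covariates,
                           model = c("age", "disease", "interaction"),
                           adjust = NULL, moderated = TRUE) {
  model <- match.arg(model)
  stopifnot(is.matrix(scores), all(colnames(scores) %in% covariates$sample_id))
  cv <- covariate_factors(covariates)
  cv <- cv[match(colnames(scores), cv$sample_id), , drop = FALSE]

  default_adjust <- switch(model,
    age = c("sex", "race", "smoking", "rin", "batch", "ischemic_time"),
    disease = c("age", "sex", "race", "smoking"),
    interaction = c("sex", "race"))
  adjust <- adjust %||% default_adjust
  usable <- vapply(adjust, function(v) {
    v %in% names(cv) && length(unique(cv[[v]][!is.na(cv[[v]])])) > 1
  }, logical(1))
  adjust <- adjust[usable]

  rhs <- switch(model,
    age = c("age", adjust),
    disease = c("disease", adjust),
    interaction = c("age * smoking", adjust))
  form <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  used_vars <- all.vars(form)
  keep <- complete.cases(cv[, used_vars, drop = FALSE])
  n_dropped <- sum(!keep)
  dat <- cv[keep, , drop = FALSE]
  dat[] <- lapply(dat, function(col) if (is.factor(col)) droplevels(col) else col)
  design <- model.matrix(form, data = dat)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("rank-deficient design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  coef_name <- switch(model, age = "age", disease = "diseasetumor",
                      interaction = "age:smokingever")
  stopifnot(coef_name %in% colnames(design))

  fit <- limma::lmFit(scores[, keep, drop = FALSE], design)
  slope <- fit$coefficients[, coef_name]
  se_unscaled <- fit$stdev.unscaled[, coef_name]
  sigma2 <- fit$sigma^2
  df <- fit$df.residual
  t_ord <- slope / (se_unscaled * fit$sigma)
  p_ord <- 2 * pt(-abs(t_ord), df)
  eb <- tryCatch(limma::eBayes(fit), error = function(e) NULL)
  if (is.null(eb)) {
    warning("variance moderation failed (degenerate variance distribution); using ordinary t")
    t_mod <- t_ord; p_mod <- p_ord
  } else {
    t_mod <- eb$t[, coef_name]
    p_mod <- eb$p.value[, coef_name]
  }
  p <- if (moderated) p_mod else p_ord
  out <- data.frame(gene = rownames(scores), slope = slope,
                    t_ordinary = t_ord, p_ordinary = p_ord,
                    t_moderated = t_mod, p_moderated = p_mod,
                    t = if (moderated) t_mod else t_ord, p = p,
                    fdr = p.adjust(p, "BH"),
                    df_residual = df, sigma2 = sigma2,
                    se_unscaled = se_unscaled,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("diff_targeting", "data.frame"),
            coef = coef_name, model = model,
            n_samples_used = sum(keep), n_dropped = n_dropped,
            design_columns = colnames(design))
}

#' @export
print.diff_targeting <- function(x, n = 6, ...) {
  cat(sprintf("differential targeting (%s coefficient): %d genes, %d samples\n",
              attr(x, "coef"), nrow(x), attr(x, "n_samples_used")))
  print.data.frame(head(x[order(x$p), ], n))
  invisible(x)
}

#' Empirical-Bayes moderation of per-gene t-statistics
#'
#' Applies the variance squeeze `s2_tilde = (d0 * s02 + d_g * s2_g) / (d0 + d_g)`
#' to a [diff_targeting()] result and recomputes t and p on `d0 + d_g`
#' degrees of freedom. The prior `(d0, s02)` is estimated by fitting a scaled
#' F-distribution to the sample variances by moments of `log s2_g` (the limma
#' scheme) unless supplied.
#'
#' @param result A `diff_targeting` data.frame.
#' @param d0,s02 Optional prior degrees of freedom and variance.
#' @return The result with `t_moderated`/`p_moderated` (and `t`, `p`, `fdr`)
#'   replaced.
#' @export
moderate_tstats <- function(result, d0 = NULL, s02 = NULL) {
  ok <- result$df_residual > 0
  if (sum(ok) < 10) stop("need at least 10 genes with positive residual df")
  if (is.null(d0) || is.null(s02)) {
    fd <- tryCatch(limma::fitFDist(result$sigma2[ok], result$df_residual[ok]),
                   error = function(e) NULL)
    if (is.null(fd) || !is.finite(fd$scale) || fd$scale <= 0) {
      warning("degenerate variance distribution; returning ordinary t")
      result$t_moderated <- result$t_ordinary
      result$p_moderated <- result$p_ordinary
      return(result)
    }
    d0 <- fd$df2; s02 <- fd$scale
  }
  s2t <- if (is.infinite(d0)) rep(s02, nrow(result)) else
    (d0 * s02 + result$df_residual * result$sigma2) / (d0 + result$df_residual)
  t_mod <- result$slope / (result$se_unscaled * sqrt(s2t))
  df_tot <- pmin(d0 + result$df_residual, .Machine$double.xmax)
  result$t_moderated <- t_mod
  result$p_moderated <- 2 * pt(-abs(t_mod), df_tot)
  result$t <- result$t_moderated
  result$p <- result$p_moderated
  result$fdr <- p.adjust(result$p, "BH")
  attr(result, "prior") <- c(d0 = d0, s02 = s02)
  result
}

#' Select significantly differentially targeted genes
#'
#' Partitions genes into an up list (`p < p_threshold` and positive slope,
#' i.e. increasingly targeted) and a down list (negative slope); the
#' threshold is a strict inequality.
#'
#' @param result A `diff_targeting` data.frame.
#' @param p_threshold Significance threshold (default 0.05).
#' @return List with `up` and `down` gene-id vectors (disjoint).
#' @export
select_age_genes <- function(result, p_threshold = 0.05) {
  sig <- result$p < p_threshold
  list(up = result$gene[sig & result$slope > 0],
       down = result$gene[sig & result$slope < 0])
}

#' Wilcoxon rank-sum comparison of two statistic sets
#'
#' Mann-Whitney/Wilcoxon rank-sum test with midrank ties; exact enumeration
#' for small untied samples (both sizes <= 20), otherwise the normal
#' approximation with continuity correction. All values tied across both
#' groups gives p = 1.
#'
#' @param stats_a,stats_b Non-empty numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (of a vs b).
#' @return List with `statistic` and `p`.
#' @export
rank_sum_compare <- function(stats_a, stats_b,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(stats_a) > 0, length(stats_b) > 0)
  if (length(unique(c(stats_a, stats_b))) == 1)
    return(list(statistic = length(stats_a) * length(stats_b) / 2, p = 1))
  has_ties <- anyDuplicated(c(stats_a, stats_b)) > 0
  use_exact <- !has_ties && max(length(stats_a), length(stats_b)) <= 20
  wt <- suppressWarnings(wilcox.test(stats_a, stats_b,
                                     alternative = alternative,
                                     exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Gene-set aging trajectory by smoking history
#'
#' The per-sample TF-targeting score of a gene set is the mean indegree over
#' its genes. Samples are split into `n_bins` consecutive age groups each
#' holding an equal share of the samples (remainder samples go to the
#' earliest bins; ties in age broken by stable sample order); within each
#' bin, the median score is computed per smoking subgroup, and a least-squares
#' line of median score on bin age midpoint is fitted per subgroup.
#'
#' @param scores Gene x sample targeting-score matrix.
#' @param gene_set Gene ids (intersected with score rows; must overlap).
#' @param covariates data.frame with `sample_id`, `age`, `smoking`.
#' @param n_bins Number of age bins (default 20, i.e. 5% of samples each).
#' @return A `trajectory` object: `bins` (bin x subgroup medians with
#'   midpoints), `lines` (per-subgroup slope and intercept), and a record of
#'   omitted empty bin-subgroup cells.
#' @export
aging_trajectory <- function(scores, gene_set, covariates, n_bins = 20) {
  genes <- intersect(gene_set, rownames(scores))
  if (length(genes) == 0) stop("gene_set does not overlap the score matrix")
  n <- ncol(scores)
  if (n < n_bins) stop("need at least ", n_bins, " samples")
  cv <- covariates[match(colnames(scores), covariates$sample_id), ]
  score <- colMeans(scores[genes, , drop = FALSE], na.rm = TRUE)

  ord <- order(cv$age)                      # stable for ties
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)

  rows <- list(); omitted <- list()
  for (b in seq_len(n_bins)) {
    in_bin <- bin == b
    mid <- (min(cv$age[in_bin]) + max(cv$age[in_bin])) / 2
    for (sm in c("never", "ever")) {
      sel <- in_bin & cv$smoking == sm
      if (!any(sel)) {
        omitted[[length(omitted) + 1]] <- data.frame(bin = b, smoking = sm)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, midpoint = mid, smoking = sm,
        median_score = median(score[sel]), n = sum(sel))
    }
  }
  bins <- do.call(rbind, rows)
  lines <- do.call(rbind, lapply(split(bins, bins$smoking), function(d) {
    fit <- lm.fit(cbind(1, d$midpoint), d$median_score)
    data.frame(smoking = d$smoking[1], intercept = fit$coefficients[1],
               slope = fit$coefficients[2], n_bins = nrow(d))
  }))
  rownames(lines) <- NULL
  structure(list(bins = bins, lines = lines,
                 omitted = if (length(omitted)) do.call(rbind, omitted) else NULL),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("aging trajectory (median gene-set targeting score by age bin):\n")
  print(x$lines)
  invisible(x)
}
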