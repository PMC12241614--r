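#' Pathway targeting score (first principal component of pathway indegrees)
#'
#' Projects samples onto the leading principal axis of the centered
#' (samples x pathway-genes) indegree submatrix. The sign is oriented so the
#' score correlates positively with the mean pathway indegree; a single-gene
#' pathway degenerates to that gene's centered indegree.
#'
#' @param scores Gene x sample targeting-score matrix.
#' @param pathway Gene-id vector (>= 1 present in `scores`).
#' @return Numeric per-sample score (mean ~ 0) with attributes `flipped`
#'   (orientation flag) and `var_explained`.
#' @export
pathway_score <- function(scores, pathway) {
  genes <- intersect(pathway, rownames(scores))
  if (length(genes) == 0) stop("no pathway genes present in the score matrix")
  sub <- t(scores[genes, , drop = FALSE])        # samples x genes
  if (ncol(sub) == 1) {
    v <- drop(scale(sub, scale = FALSE))
    return(structure(setNames(v, rownames(sub)), flipped = FALSE,
                     var_explained = 1))
  }
  stopifnot(nrow(sub) >= 3)
  pr <- prcomp(sub, center = TRUE, scale. = FALSE)
  v <- pr$x[, 1]
  flipped <- FALSE
  r <- suppressWarnings(cor(v, rowMeans(sub)))
  if (is.finite(r) && r < 0) { v <- -v; flipped <- TRUE }
  structure(setNames(v, rownames(sub)), flipped = flipped,
            var_explained = unname(pr$sdev[1]^2 / sum(pr$sdev^2)))
}

#' Pathway x sample targeting-score matrix
#'
#' @param scores Gene x sample targeting-score matrix.
#' @param gene_sets Named list of pathways.
#' @return Pathway x sample matrix of first-PC targeting scores, with an
#'   `orientation` attribute of per-pathway flip flags.
#' @export
pathway_score_matrix <- function(scores, gene_sets) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  rows <- lapply(gene_sets, function(g) pathway_score(scores, g))
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(gene_sets), colnames(scores))
  attr(out, "orientation") <- vapply(rows, attr, logical(1), "flipped")
  out
}

#' Fit a LASSO-penalized Cox aging signature
#'
#' L1-penalized Cox partial likelihood (Breslow ties) over pathway targeting
#' scores, maximized by cyclic coordinate descent along a log-spaced lambda
#' path; K-fold cross-validation on the partial-likelihood deviance selects
#' the largest lambda whose CV error is within one standard error of the
#' minimum (the lambda-1SE rule, favoring sparse models). Predictors are
#' standardized internally; coefficients are returned on the original scale.
#'
#' @param X Pathway x sample score matrix (candidate pathways).
#' @param time,event Survival time and event indicator (0/1); at least one
#'   event required, and every CV fold must contain an event.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param lambda Optional fixed penalty; skips cross-validation and fits at
#'   this value (0 gives the unpenalized partial-likelihood maximum).
#' @return An `aging_signature` model: selected pathways and coefficients,
#'   lambda path with CV curve (mean deviance +/- SE), chosen lambda, fold
#'   seed. Methods: `coef`, `predict`, `print`, `summary`.
#' @export
aging_signature_fit <- function(X, time, event, n_folds = 10, seed = 1L,
                                lambda_rule = c("1se", "min"), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.matrix(X), ncol(X) == length(time), length(time) == length(event),
            all(event %in% c(0, 1)), all(time > 0))
  if (sum(event) == 0) stop("no events: cannot fit a survival model")
  x <- t(X)
  y <- survival::Surv(time, event)
  if (!is.null(lambda)) {
    stopifnot(length(lambda) == 1, lambda >= 0)
    # descending path ending at the requested lambda keeps the coordinate
    # descent warm-started and numerically tight
    path <- sort(unique(c(lambda, lambda + c(4, 2, 1, 0.5, 0.1))),
                 decreasing = TRUE)
    xx <- if (ncol(x) == 1) cbind(x, .pad = 0) else x  # glmnet needs >= 2 cols
    fit <- glmnet::glmnet(xx, y, family = "cox", lambda = path,
                          standardize = TRUE, thresh = 1e-14)
    cf <- as.matrix(coef(fit, s = lambda, exact = FALSE))[, 1]
    cf <- cf[names(cf) != ".pad"]
    return(structure(list(candidates = rownames(X),
                          coefficients = cf[cf != 0],
                          selected = names(cf)[cf != 0],
                          lambda = lambda, lambda_rule = "fixed",
                          cv_curve = NULL, n_folds = NA_integer_,
                          fold_seed = seed, n_events = sum(event),
                          n_samples = length(time), glmnet_fit = fit),
                     class = "aging_signature"))
  }
  foldid <- with_seed(seed, {
    for (try in 1:100) {
      f <- sample(rep(seq_len(n_folds), length.out = length(time)))
      if (all(tapply(event, f, sum) >= 1)) break
    }
    if (!all(tapply(event, f, sum) >= 1))
      stop("could not form cross-validation folds with at least one event each")
    f
  })
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                          standardize = TRUE)
  lambda <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  cf <- as.matrix(coef(cv, s = lambda))[, 1]
  selected <- names(cf)[cf != 0]
  structure(list(candidates = rownames(X),
                 coefficients = cf[cf != 0],
                 selected = selected,
                 lambda = lambda, lambda_rule = lambda_rule,
                 cv_curve = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                                       cvsd = cv$cvsd, nzero = cv$nzero),
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 n_folds = n_folds, fold_seed = seed,
                 n_events = sum(event), n_samples = length(time),
                 glmnet_fit = cv$glmnet.fit),
            class = "aging_signature")
}

#' @export
print.aging_signature <- function(x, ...) {
  cat(sprintf("aging signature: %d of %d candidate pathways selected (lambda %s = %.4g)\n",
              length(x$selected), length(x$candidates), x$lambda_rule, x$lambda))
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.aging_signature <- function(object, ...) {
  cat(sprintf("Penalized Cox aging signature (%d samples, %d events, %d-fold CV)\n",
              object$n_samples, object$n_events, object$n_folds))
  print(object)
  i <- which.min(abs(object$cv_curve$lambda - object$lambda))
  cat(sprintf("CV deviance at chosen lambda: %.4g +/- %.4g\n",
              object$cv_curve$cvm[i], object$cv_curve$cvsd[i]))
  invisible(object)
}

#' @export
coef.aging_signature <- function(object, ...) object$coefficients

#' Compute the aging signature (linear predictor) for samples
#'
#' `signature = sum over selected pathways of coefficient * pathway score`.
#' Columns for non-selected pathways are ignored; missing selected pathways
#' are an error. An empty model gives a constant zero signature.
#'
#' @param object An `aging_signature` model.
#' @param newX Pathway x sample score matrix covering the selected pathways.
#' @param ... Unused.
#' @return Named numeric vector, one value per sample.
#' @export
predict.aging_signature <- function(object, newX, ...) {
  stopifnot(is.matrix(newX))
  if (length(object$coefficients) == 0)
    return(setNames(rep(0, ncol(newX)), colnames(newX)))
  missing <- setdiff(object$selected, rownames(newX))
  if (length(missing))
    stop("missing pathway scores: ", paste(missing, collapse = ", "))
  drop(crossprod(newX[object$selected, , drop = FALSE], object$coefficients))
}

#' Kaplan-Meier curves and log-rank test for a median split
#'
#' Splits samples into low/high groups at the median of `score` (values
#' strictly above the median are "high"; ties go to the low group), computes
#' the product-limit survival estimate per group and the two-group log-rank
#' chi-square on 1 df. A binary grouping can be supplied directly. With zero
#' events overall, p = 1 and the curves are flat.
#'
#' @param time,event Survival data.
#' @param score Numeric score to median-split, or a two-level grouping.
#' @return A `km_logrank` list: `fit` (a [survival::survfit] object),
#'   `group`, `chisq`, `p`.
#' @export
km_logrank <- function(time, event, score) {
  stopifnot(length(time) == length(event), length(event) == length(score))
  if (is.numeric(score)) {
    group <- factor(ifelse(score > median(score), "high", "low"),
                    c("low", "high"))
  } else {
    group <- factor(score)
  }
  if (nlevels(droplevels(group)) < 2) stop("both groups must be non-empty")
  d <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (sum(event) == 0)
    return(structure(list(fit = fit, group = group, chisq = 0, p = 1),
                     class = "km_logrank"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  structure(list(fit = fit, group = group, chisq = sd$chisq,
                 p = pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.3f (1 df), p = %.4g\n", x$chisq, x$p))
  invisible(x)
}

#' Covariate-adjusted Cox proportional-hazards fit
#'
#' Unpenalized Cox partial likelihood (Breslow ties by default) by
#' Newton-Raphson, with per-coefficient Wald tests. Thin wrapper around
#' [survival::coxph()] for evaluating the aging signature alongside clinical
#' covariates.
#'
#' @param time,event Survival data.
#' @param covariates data.frame of covariates (including the signature).
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @return data.frame with `coef`, `se`, `z`, `p` per covariate; the fitted
#'   model is attached as attribute `fit`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(sum(event) >= 1)
  d <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = d,
                         ties = ties)
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s), coef = s[, "coef"],
                    se = s[, "se(coef)"], z = s[, "z"],
                    p = s[, "Pr(>|z|)"], row.names = NULL)
  attr(out, "fit") <- fit
  out
}
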