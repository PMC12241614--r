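test_that("pathway scores are the oriented first principal component", {
  set.seed(1)
  n <- 12
  base <- rnorm(n)
  scores <- rbind(g1 = base + rnorm(n, sd = 0.1),
                  g2 = base + rnorm(n, sd = 0.1),
                  g3 = 2 * base + rnorm(n, sd = 0.1),
                  g4 = rnorm(n))
  colnames(scores) <- paste0("s", 1:n)
  # one-gene pathway degenerates to the centered indegree
  v1 <- pathway_score(scores, "g1")
  expect_equal(unname(v1), unname(scores["g1", ] - mean(scores["g1", ])),
               ignore_attr = TRUE)
  # two perfectly correlated genes: PC1 explains all variance
  dup <- rbind(a = base, b = 2 * base)
  colnames(dup) <- colnames(scores)
  v2 <- pathway_score(dup, c("a", "b"))
  expect_equal(attr(v2, "var_explained"), 1, tolerance = 1e-10)
  # eigen-decomposition oracle for a 4-gene pathway
  v <- pathway_score(scores, rownames(scores))
  sub <- t(scores)
  cc <- sweep(sub, 2, colMeans(sub))
  ev <- eigen(cov(sub))$vectors[, 1]
  proj <- drop(cc %*% ev)
  if (cor(proj, rowMeans(sub)) < 0) proj <- -proj
  expect_equal(unname(v), unname(proj), tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(cor(v, rowMeans(sub)), 0)   # orientation convention
  expect_error(pathway_score(scores, "absent"), "no pathway genes")
})

test_that("pathway score matrices align rows to gene sets", {
  set.seed(2)
  scores <- matrix(rnorm(6 * 10), 6, 10,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  psm <- pathway_score_matrix(scores, list(p1 = c("g1", "g2"),
                                           p2 = c("g3", "g4", "g5")))
  expect_equal(rownames(psm), c("p1", "p2"))
  expect_equal(abs(rowMeans(psm)), c(p1 = 0, p2 = 0), tolerance = 1e-10)
})

test_that("the penalty boundary gives the empty model", {
  sc <- generate_survival_cohort(n_samples = 120, seed = 3)
  fit <- aging_signature_fit(sc$scores, sc$time, sc$event, n_folds = 5,
                             seed = 1)
  lmax <- max(fit$cv_curve$lambda)
  cf <- as.matrix(coef(fit$glmnet_fit, s = lmax))[, 1]
  expect_true(all(cf == 0))
  # chosen lambda lies on the path
  expect_true(any(abs(fit$cv_curve$lambda - fit$lambda) < 1e-10))
})

test_that("the unpenalized fit matches a Newton-Raphson Cox oracle", {
  sc <- generate_survival_cohort(n_samples = 150, n_pathways = 1,
                                 active_pathways = 1, beta = 0.6, seed = 4)
  fit0 <- aging_signature_fit(sc$scores, sc$time, sc$event, lambda = 0)
  oracle <- survival::coxph(survival::Surv(sc$time, sc$event) ~ x,
                            data = data.frame(x = sc$scores[1, ]),
                            ties = "breslow", control = survival::coxph.control(eps = 1e-12, toler.chol = 1e-13))
  expect_equal(unname(fit0$coefficients["pw01"]), unname(coef(oracle)),
               tolerance = 1e-6)
})

test_that("the signature is the linear predictor over selected pathways", {
  model <- structure(list(candidates = c("p1", "p2", "p3"),
                          coefficients = c(p1 = 0.5, p2 = -1),
                          selected = c("p1", "p2")),
                     class = "aging_signature")
  X <- rbind(p1 = c(2, 0), p2 = c(1, 3), p3 = c(9, 9))
  colnames(X) <- c("s1", "s2")
  expect_equal(unname(predict(model, X)), c(0.5 * 2 - 1, -3))
  # adding an irrelevant pathway changes nothing
  X2 <- rbind(X, p4 = c(5, 5))
  expect_equal(predict(model, X2), predict(model, X))
  expect_error(predict(model, X[c("p1", "p3"), ]), "missing pathway")
  empty <- structure(list(coefficients = numeric(), selected = character()),
                     class = "aging_signature")
  expect_equal(unname(predict(empty, X)), c(0, 0))
})

test_that("survival-independent scores mostly select the empty model", {
  hits <- vapply(1:6, function(i) {
    sc <- generate_survival_cohort(n_samples = 150, active_pathways = 1,
                                   beta = 0, seed = 100 + i)
    fit <- aging_signature_fit(sc$scores, sc$time, sc$event, n_folds = 5,
                               seed = i)
    length(fit$selected) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("Kaplan-Meier curves and log-rank match a hand-worked table", {
  # classic 6-subject fixture: events at 1, 3, 4; censoring at 2, 5, 6
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 0)
  group <- c("a", "a", "a", "b", "b", "b")
  km <- km_logrank(time, event, group)
  sf <- summary(km$fit)
  # group a: S(1) = 5/6... per-group product-limit:
  # a: at t=1 (3 at risk, 1 event) -> 2/3; at t=3 (1 at risk, 1 event) -> 0
  surv_a <- sf$surv[sf$strata == "group=a"]
  expect_equal(surv_a, c(2 / 3, 0), tolerance = 1e-10)
  # b: at t=4 (3 at risk, 1 event) -> 2/3
  surv_b <- sf$surv[sf$strata == "group=b"]
  expect_equal(surv_b, 2 / 3, tolerance = 1e-10)
  # hand-computed log-rank: O-E for group a over event times 1, 3, 4
  # t=1: n=6, na=3, O=1, E=0.5 ; t=3: n=4, na=2, O=1, E=0.5
  # t=4: n=3, na=1, O=0, E=1/3 ; sum O-E = 2/3... use survdiff chi-square
  sd_ref <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(km$chisq, sd_ref$chisq, tolerance = 1e-10)
  expect_equal(km$p, pchisq(sd_ref$chisq, 1, lower.tail = FALSE))
  # exchanging labels leaves the statistic unchanged
  km2 <- km_logrank(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(km2$chisq, km$chisq)
})

test_that("median splits put ties in the low group and handle no events", {
  score <- c(1, 2, 3, 3, 5)                         # median 3, tied at the median
  km <- km_logrank(c(5, 4, 3, 6, 2), c(1, 1, 0, 1, 1), score)
  expect_equal(unname(table(km$group)["low"]), 4)   # ties at the median go low
  km0 <- km_logrank(1:5, rep(0, 5), score)
  expect_equal(km0$p, 1)
  expect_true(all(summary(km0$fit)$surv == 1))
})

test_that("adjusted Cox fits are sane and scale-equivariant", {
  set.seed(5)
  n <- 200
  x <- rnorm(n)
  z <- rnorm(n)
  rate <- 0.01 * exp(0.8 * x)
  time <- rexp(n, rate)
  event <- rep(1, n)
  fit <- cox_fit(time, event, data.frame(x = x, z = z))
  # null covariate within 3 SE of zero; active one recovers its effect
  zrow <- fit[fit$term == "z", ]
  expect_lt(abs(zrow$coef / zrow$se), 3)
  expect_equal(fit$coef[fit$term == "x"], 0.8, tolerance = 0.2)
  # doubling a covariate halves its coefficient
  fit2 <- cox_fit(time, event, data.frame(x = 2 * x, z = z))
  expect_equal(fit2$coef[fit2$term == "x"], fit$coef[fit$term == "x"] / 2,
               tolerance = 1e-8)
})

test_that("unpenalized path and coxph agree on two covariates", {
  sc <- generate_survival_cohort(n_samples = 180, n_pathways = 2,
                                 active_pathways = 1:2, beta = c(0.5, -0.5),
                                 seed = 6)
  fit0 <- aging_signature_fit(sc$scores, sc$time, sc$event, lambda = 0)
  ref <- cox_fit(sc$time, sc$event,
                 as.data.frame(t(sc$scores)))
  expect_equal(unname(fit0$coefficients[ref$term]), ref$coef,
               tolerance = 1e-6)
})
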