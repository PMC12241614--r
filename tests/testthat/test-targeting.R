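make_cov <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = paste0("s", seq_len(n)),
             age = runif(n, 30, 70),
             sex = sample(c("female", "male"), n, TRUE),
             smoking = sample(c("never", "ever"), n, TRUE))
}

test_that("an exact linear response is fitted without residual error", {
  cov <- make_cov(12)
  scores <- rbind(exact = 2 * cov$age,
                  matrix(rnorm(11 * 12), 11, 12,
                         dimnames = list(paste0("g", 1:11), NULL)))
  colnames(scores) <- cov$sample_id
  fit <- diff_targeting(scores, cov, model = "age", adjust = character())
  expect_equal(fit$slope[fit$gene == "exact"], 2, tolerance = 1e-10)
  expect_equal(fit$sigma2[fit$gene == "exact"], 0, tolerance = 1e-12)
})

test_that("per-gene statistics match a normal-equations oracle", {
  cov <- make_cov(8, seed = 3)
  scores <- matrix(rnorm(5 * 8), 5, 8,
                   dimnames = list(paste0("g", 1:5), cov$sample_id))
  fit <- diff_targeting(scores, cov, model = "age", adjust = "smoking",
                        moderated = FALSE)
  X <- cbind(1, cov$age, as.integer(cov$smoking == "ever"))
  XtXi <- solve(crossprod(X))
  for (g in rownames(scores)) {
    beta <- XtXi %*% crossprod(X, scores[g, ])
    res <- scores[g, ] - X %*% beta
    s2 <- sum(res^2) / (8 - 3)
    t_or <- beta[2] / sqrt(s2 * XtXi[2, 2])
    i <- which(fit$gene == g)
    expect_equal(fit$slope[i], beta[2], tolerance = 1e-8)
    expect_equal(fit$t_ordinary[i], t_or, tolerance = 1e-8)
    expect_equal(fit$p_ordinary[i], 2 * pt(-abs(t_or), 5), tolerance = 1e-8)
    expect_equal(fit$df_residual[i], 5)
  }
})

test_that("statistics are invariant to sample order", {
  cov <- make_cov(15, seed = 4)
  scores <- matrix(rnorm(6 * 15), 6, 15,
                   dimnames = list(paste0("g", 1:6), cov$sample_id))
  f1 <- diff_targeting(scores, cov, model = "age")
  perm <- sample(15)
  f2 <- diff_targeting(scores[, perm], cov, model = "age")
  expect_equal(f1$t_moderated, f2$t_moderated, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("aliased design columns raise a named error", {
  cov <- make_cov(10, seed = 5)
  cov$rin <- cov$age           # perfectly collinear with age
  scores <- matrix(rnorm(30), 3, 10,
                   dimnames = list(paste0("g", 1:3), cov$sample_id))
  expect_error(diff_targeting(scores, cov, model = "age", adjust = "rin"),
               "rank-deficient.*rin")
})

test_that("interaction and disease models expose the right coefficient", {
  cov <- make_cov(40, seed = 6)
  cov$disease <- sample(c("healthy", "tumor"), 40, TRUE)
  scores <- matrix(rnorm(8 * 40), 8, 40,
                   dimnames = list(paste0("g", 1:8), cov$sample_id))
  fit_i <- diff_targeting(scores, cov, model = "interaction",
                          adjust = character())
  expect_equal(attr(fit_i, "coef"), "age:smokingever")
  fit_d <- diff_targeting(scores, cov, model = "disease", adjust = "sex")
  expect_equal(attr(fit_d, "coef"), "diseasetumor")
  expect_true(all(fit_d$p > 0 & fit_d$p <= 1))
})

test_that("variance moderation follows the squeeze formula", {
  cov <- make_cov(20, seed = 7)
  set.seed(8)
  scores <- matrix(rnorm(20 * 20, sd = rep(c(1, 3), each = 10)), 20, 20,
                   dimnames = list(paste0("g", 1:20), cov$sample_id))
  fit <- diff_targeting(scores, cov, model = "age", adjust = character(),
                        moderated = FALSE)
  d0 <- 4; s02 <- 2
  mod <- moderate_tstats(fit, d0 = d0, s02 = s02)
  s2t <- (d0 * s02 + fit$df_residual * fit$sigma2) / (d0 + fit$df_residual)
  expect_equal(mod$t_moderated, fit$slope / (fit$se_unscaled * sqrt(s2t)),
               tolerance = 1e-10)
  expect_equal(mod$p_moderated,
               2 * pt(-abs(mod$t_moderated), d0 + fit$df_residual),
               tolerance = 1e-10)
  # no-shrinkage limit: d0 -> 0 returns the ordinary t
  mod0 <- moderate_tstats(fit, d0 = 1e-12, s02 = 2)
  expect_equal(mod0$t_moderated, fit$t_ordinary, tolerance = 1e-4)
  # equal variances: squeeze leaves t unchanged when the target equals s2
  modeq <- moderate_tstats(fit, d0 = Inf, s02 = NULL)
  expect_true(all(is.finite(modeq$t_moderated)))
})

test_that("moderated t agrees with the limma reference on a shared design", {
  cov <- make_cov(18, seed = 9)
  scores <- matrix(rnorm(30 * 18), 30, 18,
                   dimnames = list(paste0("g", 1:30), cov$sample_id))
  fit <- diff_targeting(scores, cov, model = "age", adjust = "sex")
  X <- model.matrix(~ age + sex, data.frame(age = cov$age,
                                            sex = factor(cov$sex, c("female", "male"))))
  eb <- limma::eBayes(limma::lmFit(scores, X))
  expect_equal(fit$t_moderated, unname(eb$t[, "age"]), tolerance = 1e-8)
  expect_equal(fit$p_moderated, unname(eb$p.value[, "age"]), tolerance = 1e-8)
})

test_that("significant gene selection partitions by slope sign strictly", {
  res <- data.frame(gene = paste0("g", 1:6),
                    slope = c(1, -1, 2, -2, 0.5, 1),
                    p = c(0.01, 0.02, 0.05, 0.2, 0.049, 1))
  sel <- select_age_genes(res, 0.05)
  expect_equal(sel$up, c("g1", "g5"))      # p = 0.05 excluded (strict)
  expect_equal(sel$down, "g2")
  expect_length(intersect(sel$up, sel$down), 0)
  none <- select_age_genes(transform(res, p = 1), 0.05)
  expect_length(none$up, 0)
  expect_length(none$down, 0)
})

test_that("rank-sum comparison matches exact enumeration and symmetry", {
  r <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$p, 1 / choose(6, 3))
  # swapping groups mirrors the one-sided test under exactness
  r2 <- rank_sum_compare(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(r2$p, r$p)
  # identical tied groups
  expect_equal(rank_sum_compare(rep(1, 4), rep(1, 5))$p, 1)
  # large-sample normal approximation stays in (0, 1]
  set.seed(10)
  big <- rank_sum_compare(rnorm(50), rnorm(60) + 0.5, "less")
  expect_true(big$p > 0 && big$p < 1)
})

test_that("aging trajectories bin, summarize and fit as specified", {
  n <- 40
  cov <- data.frame(sample_id = paste0("s", 1:n),
                    age = seq(30, 69, length.out = n),
                    smoking = rep(c("never", "ever"), n / 2))
  # constant scores: all medians equal, zero slopes
  scores <- matrix(5, 3, n, dimnames = list(paste0("g", 1:3), cov$sample_id))
  tr <- aging_trajectory(scores, paste0("g", 1:3), cov, n_bins = 20)
  expect_true(all(tr$bins$median_score == 5))
  expect_equal(tr$lines$slope, c(0, 0), tolerance = 1e-12)
  # binning oracle: 40 samples over 20 bins -> 2 per bin, sorted by age
  expect_true(all(tr$bins$n <= 2))
  expect_equal(sum(tr$bins$n), n)
  # planted smoking acceleration: ever-smokers gain score faster with age
  set.seed(11)
  accel <- ifelse(cov$smoking == "ever", 2, 1)
  s2 <- matrix(rep(cov$age * accel, each = 3), 3, n,
               dimnames = dimnames(scores)) + rnorm(3 * n, sd = 2)
  colnames(s2) <- cov$sample_id
  tr2 <- aging_trajectory(s2, paste0("g", 1:3), cov, n_bins = 20)
  expect_gt(tr2$lines$slope[tr2$lines$smoking == "ever"],
            tr2$lines$slope[tr2$lines$smoking == "never"])
})

test_that("trajectory bin midpoints come from a sorting oracle", {
  set.seed(12)
  n <- 47   # non-divisible: remainder goes to earliest bins
  cov <- data.frame(sample_id = paste0("s", 1:n), age = runif(n, 25, 75),
                    smoking = sample(c("never", "ever"), n, TRUE))
  scores <- matrix(rnorm(2 * n), 2, n,
                   dimnames = list(c("g1", "g2"), cov$sample_id))
  tr <- aging_trajectory(scores, c("g1", "g2"), cov, n_bins = 20)
  sizes <- tapply(tr$bins$n, tr$bins$bin, sum)
  expect_equal(as.vector(sizes[1:7]), rep(3, 7))   # 47 = 7*3 + 13*2
  expect_true(all(sizes[8:20] == 2))
  ord_ages <- sort(cov$age)
  first_bin <- ord_ages[1:3]
  expect_equal(unique(tr$bins$midpoint[tr$bins$bin == 1]),
               (min(first_bin) + max(first_bin)) / 2)
})
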