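test_that("promoter-window overlap defines motif prior edges", {
  ann <- data.frame(gene_id = "g1", chromosome = "chr1", strand = "+",
                    tss = 10000L)
  hit_in <- data.frame(tf_id = "tf1", chromosome = "chr1", start = 9500L,
                       end = 9510L, p_value = 1e-6)
  hit_out <- data.frame(tf_id = "tf1", chromosome = "chr1", start = 8000L,
                        end = 8010L, p_value = 1e-6)
  expect_equal(build_motif_prior(hit_in, ann)$edges["tf1", "g1"], 1)
  expect_equal(build_motif_prior(hit_out, ann)$edges["tf1", "g1"], 0)
  # window edges are inclusive: [tss - 750, tss + 250]
  edge_hit <- data.frame(tf_id = "tf1", chromosome = "chr1", start = 9000L,
                         end = 9250L, p_value = 1e-6)
  expect_equal(build_motif_prior(edge_hit, ann)$edges["tf1", "g1"], 1)
  # non-significant hit is dropped (strict threshold)
  weak <- transform(hit_in, p_value = 1e-5)
  expect_equal(build_motif_prior(weak, ann)$edges["tf1", "g1"], 0)
})

test_that("minus-strand promoter windows are mirrored", {
  ann <- data.frame(gene_id = "g1", chromosome = "chr1", strand = "-",
                    tss = 10000L)
  # upstream of a minus-strand gene lies at larger coordinates
  up_hit <- data.frame(tf_id = "tf1", chromosome = "chr1", start = 10700L,
                       end = 10710L, p_value = 1e-6)
  down_hit <- data.frame(tf_id = "tf1", chromosome = "chr1", start = 9800L,
                         end = 9810L, p_value = 1e-6)
  far <- data.frame(tf_id = "tf1", chromosome = "chr1", start = 9000L,
                    end = 9100L, p_value = 1e-6)
  expect_equal(build_motif_prior(up_hit, ann)$edges[1, 1], 1)
  expect_equal(build_motif_prior(down_hit, ann)$edges[1, 1], 1)
  expect_equal(build_motif_prior(far, ann)$edges[1, 1], 0)
})

test_that("motif prior matches a brute-force interval oracle on mixed hits", {
  ann <- toy_annotations()
  set.seed(3)
  hits <- data.frame(
    tf_id = sample(c("tf1", "tf2", "tf3"), 7, TRUE),
    chromosome = sample(c("chr1", "chr2", "chrY"), 7, TRUE),
    start = sample.int(25000, 7), p_value = c(1e-6, 1e-7, 1e-4, 1e-6, 1e-8,
                                              1e-6, 0.5))
  hits$end <- hits$start + sample.int(400, 7)
  prior <- build_motif_prior(hits, ann, upstream = 750, downstream = 250,
                             p_threshold = 1e-5)
  # independent exhaustive check
  for (tf in prior$tfs) for (g in ann$gene_id) {
    a <- ann[ann$gene_id == g, ]
    lo <- if (a$strand == "+") a$tss - 750 else a$tss - 250
    hi <- if (a$strand == "+") a$tss + 250 else a$tss + 750
    expected <- 0
    for (k in seq_len(nrow(hits))) {
      h <- hits[k, ]
      if (h$tf_id == tf && h$chromosome == a$chromosome &&
          h$p_value < 1e-5 && h$start <= hi && h$end >= lo) expected <- 1
    }
    expect_equal(unname(prior$edges[tf, g]), expected,
                 info = paste(tf, g))
  }
})

test_that("empty hit lists and unknown chromosomes are handled", {
  ann <- toy_annotations()
  empty <- build_motif_prior(data.frame(tf_id = character(),
                                        chromosome = character(),
                                        start = integer(), end = integer(),
                                        p_value = numeric()),
                             ann, tfs = c("tf1", "tf2"))
  expect_true(all(empty$edges == 0))
  bad <- data.frame(tf_id = "tf1", chromosome = "chrM", start = 1L,
                    end = 10L, p_value = 1e-8)
  expect_warning(p <- build_motif_prior(bad, ann), "ignored")
  expect_true(all(p$edges == 0))
})

test_that("motif prior is idempotent under rebuilding from induced hits", {
  ann <- toy_annotations()
  prior <- toy_motif_prior()
  # place one synthetic significant hit at each edge's promoter
  idx <- which(prior$edges == 1, arr.ind = TRUE)
  hits <- data.frame(tf_id = prior$tfs[idx[, 1]],
                     chromosome = ann$chromosome[idx[, 2]],
                     start = ann$tss[idx[, 2]], end = ann$tss[idx[, 2]],
                     p_value = 1e-9)
  rebuilt <- build_motif_prior(hits, ann, tfs = prior$tfs)
  expect_equal(rebuilt$edges, prior$edges)
})

test_that("female prior zeroes exactly the chrY-incident edges", {
  ann <- toy_annotations()
  prior <- toy_motif_prior()
  chry_edges <- sum(prior$edges[, c("gY1", "gY2")])
  expect_gt(chry_edges, 0)
  fem <- make_sex_specific_prior(prior, "female", ann)
  expect_true(all(fem$edges[, c("gY1", "gY2")] == 0))
  expect_equal(fem$edges[, c("gA", "gB", "gC", "gD")],
               prior$edges[, c("gA", "gB", "gC", "gD")])
  expect_equal(sum(prior$edges) - sum(fem$edges), chry_edges)
  # male prior unchanged; zeroing never adds edges
  expect_identical(make_sex_specific_prior(prior, "male", ann), prior)
  expect_true(all(fem$edges <= prior$edges))
})

test_that("PPI prior normalizes, symmetrizes by max and sets unit diagonal", {
  tfs <- c("A", "B", "C")
  p1 <- build_ppi_prior(data.frame(tf_a = "A", tf_b = "B", score = 800), tfs)
  expect_equal(p1$scores["A", "B"], 0.8)
  expect_equal(p1$scores["B", "A"], 0.8)
  empty <- build_ppi_prior(data.frame(tf_a = character(), tf_b = character(),
                                      score = numeric()), tfs)
  expect_equal(unname(empty$scores), diag(3))
  both <- build_ppi_prior(data.frame(tf_a = c("A", "B"), tf_b = c("B", "A"),
                                     score = c(600, 900)), tfs)
  expect_equal(both$scores["A", "B"], 0.9)
  expect_equal(both$scores["B", "A"], 0.9)
  expect_error(build_ppi_prior(data.frame(tf_a = "A", tf_b = "B",
                                          score = 1500), tfs), "\\[0, 1000\\]")
})

test_that("PPI prior is symmetric with unit diagonal on random inputs", {
  set.seed(9)
  tfs <- paste0("tf", 1:8)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    inter <- data.frame(tf_a = sample(tfs, n, TRUE),
                        tf_b = sample(tfs, n, TRUE),
                        score = runif(n, 0, 1000))
    p <- build_ppi_prior(inter, tfs)
    expect_equal(p$scores, t(p$scores))
    expect_equal(unname(diag(p$scores)), rep(1, 8))
    expect_true(all(p$scores >= 0 & p$scores <= 1))
  }
})

test_that("expression filter drops genes below threshold in enough samples", {
  ann <- toy_annotations()
  cov <- data.frame(sample_id = paste0("s", 1:10),
                    sex = rep(c("male", "female"), 5))
  x <- matrix(5, 3, 10, dimnames = list(c("gA", "gB", "gC"), cov$sample_id))
  x["gA", 1:2] <- 0.5        # below 1 TPM in 2 of 10 samples -> dropped (2 >= 1)
  out <- preprocess_expression(x, cov, tpm_threshold = 1, sample_fraction = 0.10,
                               prior_genes = rownames(x), annotations = ann)
  expect_equal(rownames(out), c("gB", "gC"))
  # all values above threshold: nothing removed
  out2 <- preprocess_expression(matrix(5, 3, 10, dimnames = dimnames(x)), cov,
                                prior_genes = rownames(x), annotations = ann)
  expect_equal(nrow(out2), 3)
})

test_that("expression filter matches a per-gene counting oracle and handles chrY", {
  ann <- toy_annotations()
  cov <- data.frame(sample_id = paste0("s", 1:10),
                    sex = rep(c("male", "female"), each = 5))
  set.seed(11)
  x <- matrix(runif(60, 0, 4), 6, 10,
              dimnames = list(ann$gene_id, cov$sample_id))
  out <- preprocess_expression(x, cov, tpm_threshold = 1, sample_fraction = 0.2,
                               prior_genes = ann$gene_id, annotations = ann)
  keep_oracle <- apply(x, 1, function(v) sum(v < 1) < 0.2 * 10)
  expect_equal(rownames(out), rownames(x)[keep_oracle])
  # chrY genes are NA for female samples only
  if (any(rownames(out) %in% c("gY1", "gY2"))) {
    y <- out[rownames(out) %in% c("gY1", "gY2"), , drop = FALSE]
    expect_true(all(is.na(y[, cov$sex == "female"])))
    expect_true(all(!is.na(y[, cov$sex == "male"])))
  }
  expect_error(preprocess_expression(x, cov, prior_genes = "nope",
                                     annotations = ann), "no genes")
})
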