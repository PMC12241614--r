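#' Specify a synthetic cohort with planted regulatory aging effects
#'
#' The generator emulates the statistical structure of an aging lung cohort:
#' latent TF activities drive target-gene expression through the motif prior,
#' and the TF-to-gene coupling strength of planted genes changes linearly
#' with age (faster in ever-smokers), so that the age signal is carried by
#' co-regulation strength — the quantity single-sample network indegrees
#' detect. chrY gene expression is missing for female samples. Survival times
#' follow a proportional-hazards model (exponential baseline) on true
#' pathway activity, with independent exponential censoring tuned to the
#' requested censoring fraction.
#'
#' @param n_tfs,n_genes,n_samples Cohort dimensions.
#' @param n_chrY_genes Number of genes placed on chrY (must be < `n_genes`).
#' @param age_range Age range in years, sampled uniformly.
#' @param frac_smokers,frac_female Proportions in `[0, 1]`.
#' @param planted_up_genes,planted_down_genes Disjoint gene-id lists whose
#'   TF coupling increases (resp. decreases) with age.
#' @param age_slope Coupling-strength change per year of age (> 0 plants an
#'   effect; 0 gives a null cohort).
#' @param smoking_acceleration Multiplicative factor (>= 1) applied to
#'   `age_slope` in ever-smokers.
#' @param noise_sd Private (non-co-regulated) expression noise SD (> 0).
#' @param base_coupling Baseline of the age-varying coupling of planted
#'   genes (unplanted genes have fixed coupling 1).
#' @param n_hub_tfs Number of dedicated aging-program TFs regulating each
#'   planted set (planted genes share regulators so the age effect is
#'   carried by co-regulation strength).
#' @param tf_per_gene Range of regulators per unplanted gene in the motif
#'   prior.
#' @param n_pathways,pathway_size Gene set collection layout; planted gene
#'   lists become their own pathways.
#' @param survival_beta Named per-pathway log-hazard coefficients (default:
#'   all zero, survival independent of regulation).
#' @param censor_rate Target censoring proportion in `[0, 1]`.
#' @param baseline_hazard Exponential baseline hazard (events per day).
#' @param seed Integer root seed; sub-streams are derived in a fixed order
#'   (structure, covariates, activities, noise, survival, censoring, drugs).
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_tfs = 20, n_genes = 200, n_samples = 120,
                        n_chrY_genes = 5, age_range = c(25, 75),
                        frac_smokers = 0.5, frac_female = 0.5,
                        planted_up_genes = character(),
                        planted_down_genes = character(),
                        age_slope = 0.02, smoking_acceleration = 1.5,
                        noise_sd = 2, base_coupling = 0,
                        n_hub_tfs = 2, tf_per_gene = c(1, 3), n_pathways = 12,
                        pathway_size = c(16, 30), survival_beta = NULL,
                        censor_rate = 0.3, baseline_hazard = 1 / 1000,
                        seed = 1L) {
  spec <- list(n_tfs = n_tfs, n_genes = n_genes, n_samples = n_samples,
               n_chrY_genes = n_chrY_genes, age_range = age_range,
               frac_smokers = frac_smokers, frac_female = frac_female,
               planted_up_genes = planted_up_genes,
               planted_down_genes = planted_down_genes,
               age_slope = age_slope,
               smoking_acceleration = smoking_acceleration,
               noise_sd = noise_sd, base_coupling = base_coupling,
               n_hub_tfs = n_hub_tfs,
               tf_per_gene = tf_per_gene, n_pathways = n_pathways,
               pathway_size = pathway_size, survival_beta = survival_beta,
               censor_rate = censor_rate, baseline_hazard = baseline_hazard,
               seed = seed)
  check_field(n_tfs >= 2, "n_tfs", "need at least 2 TFs")
  check_field(n_genes >= 4, "n_genes", "need at least 4 genes")
  check_field(n_samples >= 4, "n_samples", "need at least 4 samples")
  check_field(n_chrY_genes >= 0 && n_chrY_genes < n_genes, "n_chrY_genes",
              "must be nonnegative and < n_genes")
  check_field(length(age_range) == 2 && age_range[1] > 0 &&
                age_range[2] > age_range[1], "age_range",
              "must be increasing positive (years, years)")
  check_field(frac_smokers >= 0 && frac_smokers <= 1, "frac_smokers", "proportion in [0,1]")
  check_field(frac_female >= 0 && frac_female <= 1, "frac_female", "proportion in [0,1]")
  check_field(length(intersect(planted_up_genes, planted_down_genes)) == 0,
              "planted_up_genes", "planted gene sets must be disjoint")
  check_field(age_slope >= 0, "age_slope", "must be >= 0")
  check_field(smoking_acceleration >= 1, "smoking_acceleration", "must be >= 1")
  check_field(noise_sd > 0, "noise_sd", "must be > 0")
  check_field(censor_rate >= 0 && censor_rate < 1, "censor_rate", "proportion in [0,1)")
  structure(spec, class = "cohort_spec")
}

#' Pick default planted gene ids for a cohort spec
#'
#' Convenience helper: plants the first `n_up` autosomal genes as increasingly
#' targeted and the next `n_down` as decreasingly targeted.
#' @param spec A `cohort_spec`.
#' @param n_up,n_down Planted set sizes.
#' @return The spec with planted gene lists filled in.
#' @export
plant_genes <- function(spec, n_up = 15, n_down = 10) {
  ids <- gene_ids(spec)
  auto <- ids[seq_len(spec$n_genes - spec$n_chrY_genes)]
  stopifnot(n_up + n_down <= length(auto))
  spec$planted_up_genes <- auto[seq_len(n_up)]
  spec$planted_down_genes <- auto[n_up + seq_len(n_down)]
  spec
}

gene_ids <- function(spec) sprintf("g%04d", seq_len(spec$n_genes))
tf_ids <- function(spec) sprintf("tf%03d", seq_len(spec$n_tfs))

#' Generate a complete synthetic cohort
#'
#' Produces every input the analysis pipeline consumes — expression, motif
#' and PPI priors, gene annotations, covariates with survival, gene sets and
#' a drug signature library — plus a `truth` record sufficient to score
#' recovery of the planted effects. Identical seeds give bit-identical
#' cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` list.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(spec$seed, 7)
  genes <- gene_ids(spec)
  tfs <- tf_ids(spec)
  chry <- if (spec$n_chrY_genes > 0) genes[spec$n_genes - spec$n_chrY_genes + seq_len(spec$n_chrY_genes)] else character()
  stopifnot(all(spec$planted_up_genes %in% setdiff(genes, chry)),
            all(spec$planted_down_genes %in% setdiff(genes, chry)))

  # -- stream 1: structure (annotation, motif prior, PPI, pathways) --------
  planted <- length(spec$planted_up_genes) > 0 || length(spec$planted_down_genes) > 0
  n_hub <- if (planted) 2L * spec$n_hub_tfs else 0L
  stopifnot(n_hub + 2 <= spec$n_tfs)
  structure_bits <- with_seed(seeds[1], {
    chrom <- ifelse(genes %in% chry, "chrY",
                    paste0("chr", sample(1:22, spec$n_genes, replace = TRUE)))
    ann <- data.frame(gene_id = genes, chromosome = chrom,
                      strand = sample(c("+", "-"), spec$n_genes, TRUE),
                      tss = sample.int(1e8, spec$n_genes) + 1000L)
    M <- matrix(0, spec$n_tfs, spec$n_genes, dimnames = list(tfs, genes))
    pool <- seq(n_hub + 1L, spec$n_tfs)   # hubs reserved for planted sets
    for (j in seq_len(spec$n_genes)) {
      k <- sample(seq(spec$tf_per_gene[1], spec$tf_per_gene[2]), 1)
      M[sample(pool, min(k, length(pool))), j] <- 1
    }
    if (planted) {
      # planted genes are co-regulated by direction-specific aging-program
      # TFs, so the age effect is carried by co-regulation strength
      M[, genes %in% c(spec$planted_up_genes, spec$planted_down_genes)] <- 0
      M[seq_len(spec$n_hub_tfs), genes %in% spec$planted_up_genes] <- 1
      M[spec$n_hub_tfs + seq_len(spec$n_hub_tfs),
        genes %in% spec$planted_down_genes] <- 1
    }
    P <- matrix(0, spec$n_tfs, spec$n_tfs, dimnames = list(tfs, tfs))
    pairs <- which(upper.tri(P))
    on <- pairs[runif(length(pairs)) < 0.2]
    P[on] <- runif(length(on))
    P <- pmax(P, t(P)); diag(P) <- 1
    sets <- list()
    if (length(spec$planted_up_genes) >= 2) sets$planted_up <- spec$planted_up_genes
    if (length(spec$planted_down_genes) >= 2) sets$planted_down <- spec$planted_down_genes
    while (length(sets) < spec$n_pathways) {
      sz <- sample(seq(spec$pathway_size[1], spec$pathway_size[2]), 1)
      sets[[sprintf("pw%02d", length(sets) + 1)]] <-
        sample(genes, min(sz, spec$n_genes))
    }
    list(ann = ann, M = M, P = P, sets = sets)
  })
  ann <- structure_bits$ann

  # -- stream 2: covariates ------------------------------------------------
  covariates <- with_seed(seeds[2], {
    data.frame(
      sample_id = sprintf("s%04d", seq_len(spec$n_samples)),
      age = round(runif(spec$n_samples, spec$age_range[1], spec$age_range[2]), 1),
      sex = ifelse(runif(spec$n_samples) < spec$frac_female, "female", "male"),
      race = sample(c("white", "black", "other"), spec$n_samples, TRUE,
                    prob = c(0.8, 0.15, 0.05)),
      smoking = ifelse(runif(spec$n_samples) < spec$frac_smokers, "ever", "never"),
      disease = "healthy",
      stage = NA_character_,
      batch = sample(c("b1", "b2"), spec$n_samples, TRUE),
      rin = round(runif(spec$n_samples, 6, 10), 1),
      ischemic_time = round(runif(spec$n_samples, 0, 24), 2),
      stringsAsFactors = FALSE)
  })

  # -- streams 3-4: TF activities and expression ---------------------------
  A <- with_seed(seeds[3], matrix(rnorm(spec$n_tfs * spec$n_samples),
                                  spec$n_tfs, spec$n_samples,
                                  dimnames = list(tfs, covariates$sample_id)))
  accel <- ifelse(covariates$smoking == "ever", spec$smoking_acceleration, 1)
  # planted-up coupling grows with age; planted-down mirrors the decline
  # across the age range; unplanted genes have fixed unit coupling
  b_up <- spec$base_coupling + spec$age_slope * covariates$age * accel
  b_down <- spec$base_coupling +
    spec$age_slope * (sum(spec$age_range) - covariates$age) * accel
  B <- matrix(1, spec$n_genes, spec$n_samples,
              dimnames = list(genes, covariates$sample_id))
  B[spec$planted_up_genes, ] <- rep(b_up, each = length(spec$planted_up_genes))
  B[spec$planted_down_genes, ] <- rep(b_down,
                                      each = length(spec$planted_down_genes))
  signal <- crossprod(structure_bits$M, A)                  # gene x sample
  noise <- with_seed(seeds[4], matrix(rnorm(spec$n_genes * spec$n_samples,
                                            sd = spec$noise_sd),
                                      spec$n_genes, spec$n_samples))
  k_reg <- colSums(structure_bits$M)                        # regulators per gene
  # standardized so the coupling modulates the co-regulated share of
  # variance (the quantity coexpression-based inference detects), not the
  # expression amplitude
  expr <- (B * signal + noise) / sqrt(B^2 * k_reg + spec$noise_sd^2)
  expr <- expr - min(expr)                                  # TPM-like nonnegative
  dimnames(expr) <- list(genes, covariates$sample_id)
  if (length(chry) && any(covariates$sex == "female"))
    expr[chry, covariates$sex == "female"] <- NA_real_

  # -- pathway activity and survival (streams 5-6) -------------------------
  sets <- structure_bits$sets
  z <- t(scale(t(ifelse(is.na(expr), 0, expr))))
  z[!is.finite(z)] <- 0
  activity <- t(vapply(sets, function(gs) colMeans(z[gs, , drop = FALSE]),
                       numeric(spec$n_samples)))
  activity <- t(scale(t(activity)))
  activity[!is.finite(activity)] <- 0
  beta <- setNames(numeric(length(sets)), names(sets))
  if (!is.null(spec$survival_beta)) {
    stopifnot(all(names(spec$survival_beta) %in% names(sets)))
    beta[names(spec$survival_beta)] <- spec$survival_beta
  }
  rate <- spec$baseline_hazard * exp(drop(crossprod(activity, beta)))
  times <- with_seed(seeds[5], rexp(spec$n_samples, rate))
  if (spec$censor_rate > 0) {
    cr <- uniroot(function(lr) mean(exp(lr) / (exp(lr) + rate)) - spec$censor_rate,
                  lower = log(min(rate)) - 20, upper = log(max(rate)) + 20)$root
    cens <- with_seed(seeds[6], rexp(spec$n_samples, exp(cr)))
  } else {
    cens <- rep(Inf, spec$n_samples)
  }
  covariates$survival_time <- round(pmin(times, cens), 2)
  covariates$event <- as.integer(times <= cens)

  # -- stream 7: drug library ----------------------------------------------
  rev_ids <- if (length(spec$planted_up_genes) && length(spec$planted_down_genes))
    "drug_reverser" else character()
  drug_library <- generate_drug_library(
    n_drugs = 20, universe = genes, reversal_drug_ids = rev_ids,
    up = spec$planted_up_genes, down = spec$planted_down_genes,
    seed = seeds[7])

  structure(list(
    expression = expr,
    motif_prior = structure(list(tfs = tfs, genes = genes,
                                 edges = structure_bits$M), class = "motif_prior"),
    ppi_prior = structure(list(tfs = tfs, scores = structure_bits$P),
                          class = "ppi_prior"),
    annotations = ann,
    covariates = covariates,
    gene_sets = sets,
    drug_library = drug_library,
    truth = list(planted_up = spec$planted_up_genes,
                 planted_down = spec$planted_down_genes,
                 age_slope = spec$age_slope,
                 smoking_acceleration = spec$smoking_acceleration,
                 pathway_activity = activity,
                 survival_beta = beta,
                 active_pathways = names(beta)[beta != 0],
                 reversal_drugs = rev_ids),
    spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d TFs, %d genes, %d samples\n",
              length(x$motif_prior$tfs), length(x$motif_prior$genes),
              nrow(x$covariates)))
  cat(sprintf("  planted: %d up / %d down genes; age slope %.3g; %d pathways\n",
              length(x$truth$planted_up), length(x$truth$planted_down),
              x$truth$age_slope, length(x$gene_sets)))
  invisible(x)
}

#' Generate a synthetic drug regulatory-signature library
#'
#' Each drug signature has disjoint `up` (more targeted under the drug) and
#' `down` (less targeted) gene sets drawn from the universe. Designated
#' reversal drugs are planted to oppose the input lists exactly: their up-set
#' contains `down` and their down-set contains `up`, padded with genes
#' outside both input lists.
#'
#' @param n_drugs Number of drugs.
#' @param universe Gene-id universe (non-empty).
#' @param reversal_drug_ids Ids (within the first `n_drugs` names or new ids)
#'   to plant as perfect reversers.
#' @param up,down Input gene lists the reversers should oppose.
#' @param seed Integer seed.
#' @param size_range Range of random signature set sizes.
#' @return Named list of `drug_signature` lists (`id`, `up`, `down`).
#' @export
generate_drug_library <- function(n_drugs, universe,
                                  reversal_drug_ids = character(),
                                  up = character(), down = character(),
                                  seed = 1L, size_range = c(20, 60)) {
  if (length(universe) == 0) stop("drug library universe must be non-empty")
  stopifnot(all(up %in% universe), all(down %in% universe),
            length(intersect(up, down)) == 0)
  with_seed(seed, {
    other <- setdiff(universe, c(up, down))
    lib <- list()
    for (id in reversal_drug_ids) {
      pad <- sample(other, min(10, max(0, length(other) - 1)))
      half <- seq_len(length(pad) %/% 2)
      lib[[id]] <- structure(list(id = id, up = union(down, pad[half]),
                                  down = union(up, pad[-half])),
                             class = "drug_signature")
    }
    i <- 0
    while (length(lib) < n_drugs) {
      i <- i + 1
      id <- sprintf("drug%03d", i)
      if (id %in% names(lib)) next
      sz <- pmin(sample(seq(size_range[1], size_range[2]), 2, replace = TRUE),
                 floor(length(universe) / 2))
      picks <- sample(universe, sum(sz))
      lib[[id]] <- structure(list(id = id, up = picks[seq_len(sz[1])],
                                  down = picks[sz[1] + seq_len(sz[2])]),
                             class = "drug_signature")
    }
    lib
  })
}

#' Generate a pathway-level survival cohort
#'
#' The survival-signature stage consumes a pathway x sample targeting-score
#' matrix; this generator produces that unit directly: independent standard
#' normal pathway scores, survival times from a proportional-hazards model
#' (exponential baseline) whose log-hazard is a linear combination of the
#' active pathways' scores, independent exponential censoring tuned to
#' `censor_rate`, and a chronological age drawn independently of the hazard.
#'
#' @param n_samples,n_pathways Dimensions.
#' @param active_pathways Indices of hazard-active pathways.
#' @param beta Log-hazard coefficients for the active pathways (recycled).
#' @param censor_rate Target censoring proportion.
#' @param baseline_hazard Events per day at score 0.
#' @param seed Integer seed.
#' @return List with `scores` (pathways x samples), `time`, `event`, `age`,
#'   and a `truth` record.
#' @export
generate_survival_cohort <- function(n_samples = 400, n_pathways = 28,
                                     active_pathways = 1:4,
                                     beta = c(0.7, 0.7, -0.7, -0.7),
                                     censor_rate = 0.3,
                                     baseline_hazard = 1 / 1000, seed = 1L) {
  stopifnot(length(active_pathways) >= 1, max(active_pathways) <= n_pathways)
  beta <- rep_len(beta, length(active_pathways))
  with_seed(seed, {
    pw <- sprintf("pw%02d", seq_len(n_pathways))
    Z <- matrix(rnorm(n_pathways * n_samples), n_pathways, n_samples,
                dimnames = list(pw, sprintf("s%04d", seq_len(n_samples))))
    eta <- drop(crossprod(Z[active_pathways, , drop = FALSE], beta))
    rate <- baseline_hazard * exp(eta)
    times <- rexp(n_samples, rate)
    if (censor_rate > 0) {
      cr <- uniroot(function(lr) mean(exp(lr) / (exp(lr) + rate)) - censor_rate,
                    lower = log(min(rate)) - 20, upper = log(max(rate)) + 20)$root
      cens <- rexp(n_samples, exp(cr))
    } else cens <- rep(Inf, n_samples)
    list(scores = Z, time = pmin(times, cens),
         event = as.integer(times <= cens),
         age = round(runif(n_samples, 40, 80), 1),
         truth = list(active_pathways = pw[active_pathways], beta = beta))
  })
}
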