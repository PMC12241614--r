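# Restrict a motif prior to the genes present in a (filtered) expression
# matrix, preserving gene order of the expression matrix.
subset_prior <- function(prior, genes) {
  stopifnot(all(genes %in% prior$genes))
  structure(list(tfs = prior$tfs, genes = genes,
                 edges = prior$edges[, genes, drop = FALSE]),
            class = "motif_prior")
}

stage_output <- function(file, root, extra = list()) {
  rel <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", root), "/?"),
             "", file)
  c(list(file = rel, md5 = unname(tools::md5sum(file))), extra)
}

#' Run the full analysis pipeline from a configuration
#'
#' Sequences the stages simulate (or load) -> priors -> networks ->
#' targeting -> gsea -> signature -> drugs, writing every intermediate
#' artifact under the output directory and a JSON manifest with seeds,
#' parameter values, row/edge counts and file checksums. Re-running with the
#' same configuration reproduces identical outputs. On stage failure the
#' manifest records partial completion before the error propagates.
#'
#' Configuration is a nested list (or path to a YAML file) with a `simulate`
#' block (fields of [cohort_spec()], plus `n_planted_up`/`n_planted_down`)
#' or an `inputs` block of file paths, optional `priors`, `panda`,
#' `targeting`, `gsea`, `signature` and `drugs` blocks, a root `seed`, and
#' `out` (output directory, overridable by `out_dir`).
#'
#' @param config Nested list or YAML file path.
#' @param out_dir Output directory (overrides `config$out`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- out_dir %||% config$out
  if (is.null(out)) stop("no output directory: set config$out or out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  seeds <- derive_seeds(seed, 4)  # cohort, gsea, signature folds, drugs

  manifest <- list(package = "netage",
                   version = as.character(utils::packageVersion("netage")),
                   seed = seed, parameters = config, stages = list())
  finish <- function(status) {
    manifest$status <<- status
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      finish("partial")
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "complete"), res$record)
    res$value
  }

  # -- simulate / load -------------------------------------------------------
  cohort <- run_stage("simulate", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      n_up <- sim$n_planted_up %||% 0
      n_down <- sim$n_planted_down %||% 0
      sim$n_planted_up <- NULL; sim$n_planted_down <- NULL
      spec <- do.call(cohort_spec, c(sim, list(seed = seeds[1])))
      if (n_up + n_down > 0) spec <- plant_genes(spec, n_up, n_down)
      ch <- generate_cohort(spec)
      files <- write_cohort(ch, file.path(out, "cohort"))
      list(value = ch,
           record = list(outputs = lapply(unname(files), stage_output, root = out),
                         n_samples = nrow(ch$covariates),
                         n_genes = length(ch$motif_prior$genes)))
    } else if (!is.null(config$inputs)) {
      inp <- config$inputs
      ann <- read_annotations_tsv(inp$annotations)
      expr <- read_expression_tsv(inp$expression)
      edges <- read.delim(inp$motif_prior, stringsAsFactors = FALSE)
      motif <- read_prior_edges(inp$motif_prior,
                                tfs = sort(unique(edges$tf)),
                                genes = rownames(expr))
      ch <- list(expression = expr,
                 covariates = read_covariates_tsv(inp$covariates),
                 annotations = ann, motif_prior = motif,
                 ppi_prior = build_ppi_prior(read_ppi_edges(inp$ppi), motif$tfs),
                 gene_sets = read_gmt(inp$gene_sets),
                 drug_library = if (!is.null(inp$drug_library))
                   read_drug_library(inp$drug_library) else NULL,
                 truth = NULL)
      list(value = ch, record = list(inputs = inp,
                                     n_samples = nrow(ch$covariates)))
    } else stop("config needs a 'simulate' or 'inputs' block")
  })

  # -- priors ----------------------------------------------------------------
  expr <- run_stage("priors", {
    pc <- config$priors %||% list()
    filtered <- preprocess_expression(
      cohort$expression, cohort$covariates,
      tpm_threshold = pc$tpm_threshold %||% 1,
      sample_fraction = pc$sample_fraction %||% 0.10,
      prior_genes = cohort$motif_prior$genes,
      annotations = cohort$annotations)
    female <- make_sex_specific_prior(cohort$motif_prior, "female",
                                      cohort$annotations)
    f1 <- write_prior_edges(female, file.path(out, "motif_prior_female.tsv"))
    f2 <- write_expression_tsv(filtered, file.path(out, "expression_filtered.tsv"))
    list(value = filtered,
         record = list(outputs = list(stage_output(f1, out), stage_output(f2, out)),
                       n_genes_kept = nrow(filtered),
                       n_genes_dropped = nrow(cohort$expression) - nrow(filtered)))
  })

  # -- networks --------------------------------------------------------------
  scores <- run_stage("networks", {
    pc <- config$panda %||% list()
    net <- infer_sample_networks(
      expr, subset_prior(cohort$motif_prior, rownames(expr)),
      cohort$ppi_prior, cohort$covariates, cohort$annotations,
      alpha = pc$alpha %||% 0.1, tolerance = pc$tolerance %||% 0.001,
      max_iterations = pc$max_iterations %||% 200)
    f <- write_expression_tsv(net$indegree, file.path(out, "indegree.tsv"))
    list(value = net$indegree,
         record = list(outputs = list(stage_output(f, out)),
                       strata = lapply(net$strata, length)))
  })

  # -- targeting -------------------------------------------------------------
  targeting <- run_stage("targeting", {
    tc <- config$targeting %||% list()
    dt <- diff_targeting(scores, cohort$covariates,
                         model = tc$model %||% "age",
                         moderated = tc$moderated %||% TRUE)
    lists <- select_age_genes(dt, tc$p_threshold %||% 0.05)
    f1 <- file.path(out, "diff_targeting.tsv")
    write.table(as.data.frame(dt), f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(out, "genes_up.txt"); writeLines(lists$up, f2)
    f3 <- file.path(out, "genes_down.txt"); writeLines(lists$down, f3)
    list(value = list(result = dt, lists = lists),
         record = list(outputs = lapply(c(f1, f2, f3), stage_output, root = out),
                       n_up = length(lists$up), n_down = length(lists$down)))
  })

  # -- gsea ------------------------------------------------------------------
  run_stage("gsea", {
    gc <- config$gsea %||% list()
    gs <- gsea_preranked(setNames(targeting$result$t, targeting$result$gene),
                         cohort$gene_sets,
                         min_size = gc$min_size %||% 15,
                         max_size = gc$max_size %||% 500,
                         n_perm = gc$n_perm %||% 10000, seed = seeds[2])
    f <- file.path(out, "gsea.tsv")
    write.table(as.data.frame(gs), f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = gs,
         record = list(outputs = list(stage_output(f, out)),
                       n_sets = nrow(gs),
                       n_significant = sum(gs$fdr < (gc$fdr_threshold %||% 0.05))))
  })

  # -- signature -------------------------------------------------------------
  run_stage("signature", {
    sc <- config$signature %||% list()
    cv <- cohort$covariates
    psm <- pathway_score_matrix(scores, cohort$gene_sets)
    train_frac <- sc$train_frac %||% 0.5
    idx <- with_seed(seeds[3],
                     sample.int(ncol(psm), floor(train_frac * ncol(psm))))
    model <- aging_signature_fit(psm[, idx, drop = FALSE],
                                 cv$survival_time[idx], cv$event[idx],
                                 n_folds = sc$n_folds %||% 10, seed = seeds[3])
    test <- setdiff(seq_len(ncol(psm)), idx)
    sig <- predict(model, psm[, test, drop = FALSE])
    f1 <- file.path(out, "aging_signature_model.json")
    jsonlite::write_json(list(candidates = model$candidates,
                              selected = model$selected,
                              coefficients = as.list(model$coefficients),
                              lambda = model$lambda,
                              cv_curve = model$cv_curve),
                         f1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f2 <- file.path(out, "aging_signature_test.tsv")
    write.table(data.frame(sample_id = colnames(psm)[test], signature = sig),
                f2, sep = "\t", quote = FALSE, row.names = FALSE)
    km_p <- if (length(model$selected) > 0 && var(sig) > 0)
      km_logrank(cv$survival_time[test], cv$event[test], sig)$p else NA_real_
    list(value = model,
         record = list(outputs = list(stage_output(f1, out), stage_output(f2, out)),
                       n_selected = length(model$selected),
                       test_logrank_p = km_p))
  })

  # -- drugs -----------------------------------------------------------------
  run_stage("drugs", {
    dc <- config$drugs %||% list()
    f <- file.path(out, "drug_matches.tsv")
    if (length(targeting$lists$up) > 0 && length(targeting$lists$down) > 0 &&
        !is.null(cohort$drug_library)) {
      md <- match_drugs(targeting$lists$up, targeting$lists$down,
                        cohort$drug_library, universe = rownames(scores),
                        n_resamples = dc$n_resamples %||% 10000,
                        seed = seeds[4])
    } else {
      md <- data.frame(drug = character(), score = numeric(), p = numeric())
    }
    write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = md,
         record = list(outputs = list(stage_output(f, out)), n_drugs = nrow(md)))
  })

  finish("complete")
  invisible(manifest)
}
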