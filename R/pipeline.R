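#' Pipeline configuration
#'
#' Collects every knob of the end-to-end demo workflow (simulate -> score ->
#' PCA/project/assign -> adjust -> evaluate) with defaults equal to the
#' documented design choices. Can be round-tripped through YAML with
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param sim a [sim_config()] describing the synthetic cohorts.
#' @param n_pcs_assign PCs used for population assignment (default 6).
#' @param n_pcs_adjust PCs used by the ancestry adjustment (default 5).
#' @param n_pcs_covariates PCs entering the covariate set (default 10).
#' @param assign_prob_threshold abstention threshold for assignment.
#' @param cutoffs tail percentile cutoffs.
#' @param maf_threshold within-population MAF exclusion threshold.
#' @param prune_window,prune_step,prune_r2 LD pruning parameters.
#' @param ambiguous strand-ambiguous SNP policy for scoring.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), n_pcs_assign = 6,
                            n_pcs_adjust = 5, n_pcs_covariates = 10,
                            assign_prob_threshold = 0.8,
                            cutoffs = c(2, 5, 10), maf_threshold = 0.01,
                            prune_window = 500, prune_step = 50,
                            prune_r2 = 0.05,
                            ambiguous = c("drop", "keep")) {
  structure(list(sim = sim, n_pcs_assign = n_pcs_assign,
                 n_pcs_adjust = n_pcs_adjust,
                 n_pcs_covariates = n_pcs_covariates,
                 assign_prob_threshold = assign_prob_threshold,
                 cutoffs = cutoffs, maf_threshold = maf_threshold,
                 prune_window = prune_window, prune_step = prune_step,
                 prune_r2 = prune_r2,
                 ambiguous = match.arg(ambiguous)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$sim <- unclass(obj$sim)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sim <- do.call(sim_config, obj$sim[setdiff(names(obj$sim), character())])
  obj$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), obj))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the end-to-end evaluation pipeline
#'
#' Orchestrates the full workflow on synthetic multi-ancestry data: simulate
#' a reference panel and an evaluation cohort, score both through the weight
#' table I/O path, LD-prune and fit reference PCA, project and assign the
#' cohort, fit the post hoc ancestry adjustment on the reference panel,
#' adjust cohort scores, and evaluate raw scores within each population plus
#' adjusted scores pooled across the cohort. All stage outputs are written as
#' plain TSV/JSON under `out_dir`, together with a manifest recording seeds,
#' stage counts and output file checksums; a rerun with the same
#' configuration is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return (invisibly) list with the per-population and pooled
#'   `metrics_report`s, the `adjustment_model`, the `pc_model`, scores and
#'   assignments.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim

  panel <- simulate_reference_panel(sim)
  cohort <- simulate_cohort(sim, frequencies = panel$frequencies)
  stage_log("simulate", nrow(panel$genotypes$dosages), " panel + ",
            nrow(cohort$genotypes$dosages), " cohort samples, ",
            ncol(cohort$genotypes$dosages), " variants")

  weights_path <- file.path(out_dir, "weights.pgs.tsv")
  write_pgs_weights(true_weight_table(cohort), weights_path)
  weights <- load_weights(weights_path, format = "pgs_catalog")

  geno <- filter_maf(cohort$genotypes, config$maf_threshold,
                     groups = cohort$population)
  stage_log("maf_filter", ncol(geno$dosages), " variants retained (",
            attr(geno, "n_removed"), " removed)")

  raw <- score_samples(weights, geno, ambiguous = config$ambiguous)
  panel_raw <- score_samples(weights, panel$genotypes,
                             ambiguous = config$ambiguous)
  stage_log("score", attr(raw, "n_variants_used"), " variants scored")

  kept <- ld_prune(panel$genotypes, config$prune_window, config$prune_step,
                   config$prune_r2)
  stage_log("ld_prune", length(kept), " variants survive pruning")
  k_pc <- max(config$n_pcs_assign, config$n_pcs_adjust,
              config$n_pcs_covariates)
  pcm <- fit_pca(panel$genotypes[, kept], K_pc = k_pc,
                 labels = panel$population)
  coords <- project_samples(pcm, geno)
  coords <- assign_population(coords, pcm, n_pcs = config$n_pcs_assign,
                              prob_threshold = config$assign_prob_threshold)
  stage_log("ancestry", sum(coords$label != "unassigned"), "/",
            nrow(coords), " samples assigned")

  ref_coords <- project_samples(pcm, panel$genotypes)
  adj_model <- fit_adjustment(panel_raw, ref_coords,
                              n_pcs = config$n_pcs_adjust)
  adjusted <- adjust_prs(adj_model, raw, coords)
  stage_log("adjust", "adjusted ", nrow(adjusted), " cohort scores")

  pc_cov <- paste0("PC", seq_len(config$n_pcs_covariates))
  covars <- cbind(cohort$covariates[, c("age", "sex", "site")],
                  coords[match(cohort$covariates$sample_id,
                               coords$sample_id), pc_cov])
  prev <- setNames(sim$prevalence, pop_names(sim))

  reports <- list()
  for (pop in pop_names(sim)) {
    sel <- cohort$population == pop
    reports[[pop]] <- evaluate_prs(
      cohort$status[sel], raw$prs[sel],
      covariates = covars[sel, , drop = FALSE],
      prevalence = prev[[pop]], cutoffs = config$cutoffs)
  }
  pooled_prev <- sum(prev * sim$n_samples) / sum(sim$n_samples)
  pooled <- evaluate_prs(cohort$status, adjusted$prs, covariates = covars,
                         prevalence = pooled_prev, cutoffs = config$cutoffs)
  stage_log("evaluate", length(reports), " population reports + pooled")

  write.table(raw, file.path(out_dir, "scores_raw.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(adjusted, file.path(out_dir, "scores_adjusted.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(coords, file.path(out_dir, "ancestry.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  save_adjustment(adj_model, file.path(out_dir, "adjustment_model.json"))
  for (pop in names(reports))
    jsonlite::write_json(report_to_list(reports[[pop]]),
                         file.path(out_dir, paste0("metrics_", pop, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report_to_list(pooled),
                       file.path(out_dir, "metrics_pooled_adjusted.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(pooled$calibration, file.path(out_dir, "calibration.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- c("weights.pgs.tsv", "scores_raw.tsv", "scores_adjusted.tsv",
               "ancestry.tsv", "adjustment_model.json", "calibration.tsv")
  manifest <- list(
    seed = sim$seed,
    n_panel = nrow(panel$genotypes$dosages),
    n_cohort = nrow(cohort$genotypes$dosages),
    n_variants = ncol(cohort$genotypes$dosages),
    n_variants_scored = attr(raw, "n_variants_used"),
    n_pruned = length(kept),
    n_assigned = sum(coords$label != "unassigned"),
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("done", "outputs written to ", out_dir)

  invisible(list(reports = reports, pooled_adjusted = pooled,
                 adjustment_model = adj_model, pc_model = pcm,
                 scores_raw = raw, scores_adjusted = adjusted,
                 ancestry = coords, cohort = cohort, panel = panel))
}

report_to_list <- function(r) {
  list(n = r$n, case_fraction = r$case_fraction, prevalence = r$prevalence,
       liability_r2 = r$liability_r2, auc = r$auc,
       or_per_sd = r$or_per_sd[c("or", "ci_low", "ci_high", "p")],
       tail = r$tail, calibration = r$calibration)
}
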