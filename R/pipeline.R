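# End-to-end orchestration: simulate -> build/filter -> cluster ->
# predict -> report, with deterministic per-stage seeds.

#' Assemble a pipeline configuration
#'
#' Every stochastic stage derives its seed deterministically from the
#' master seed (simulation: seed; proteome: seed + 1; predictors:
#' seed + 2000 / + 3000), so stages can be toggled without perturbing
#' one another.
#'
#' @param sim a `sim_config`, or NULL to use [default_sim_config()].
#' @param k clusters for the proteomic sample dendrogram cut (default 2).
#' @param alpha significance threshold for screening and pattern
#'   extraction (default 0.05).
#' @param iterations,fraction,folds,repeats stability-selection and CV
#'   parameters (defaults 10, 0.9, 10, 10).
#' @param exclude_groups groups removed for the second predictor run
#'   (default "OW").
#' @param seed master seed.
#' @param outdir output directory for TSV sidecars and report, or NULL
#'   for in-memory results only.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(sim = NULL, k = 2, alpha = 0.05,
                            iterations = 10, fraction = 0.9,
                            folds = 10, repeats = 10,
                            exclude_groups = "OW", seed = 1L,
                            outdir = NULL) {
  if (is.null(sim)) sim <- default_sim_config(seed = seed)
  structure(list(sim = sim, k = k, alpha = alpha, iterations = iterations,
                 fraction = fraction, folds = folds, repeats = repeats,
                 exclude_groups = exclude_groups, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort and proteome, filters the matrix,
#' clusters clinical profiles (Euclidean/Ward on z-scores, scored
#' against the BMI-group partition by ARI) and proteomic profiles
#' (Jaccard/Ward, cut at k), extracts the discriminative protein
#' pattern of the high-BMI cluster, and runs stability-selected BMI
#' prediction on all samples and with `exclude_groups` removed.
#'
#' @param config a `run_config`; see [pipeline_config()].
#' @param cohort,presence optional pre-built inputs overriding
#'   simulation.
#' @return a report list (also written under `config$outdir` when set).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         presence = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = config)

  if (is.null(cohort)) {
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    prot <- simulate_proteome(cohort, sim, seed = config$seed + 1L)
    presence <- prot$matrix
    report$truth <- prot$truth
  }
  stopifnot(!is.null(presence))

  report$catalog <- summarize_catalog(presence, cohort,
    merge_groups = list(OWOB = c("OW", "OB1", "OB2", "OB3")))
  filtered <- filter_proteins(presence)
  report$dim_filtered <- dim(filtered)

  # clinical component: screen, cluster on z-scores, compare to groups
  screen <- screen_parameters(cohort, alpha = config$alpha)
  report$screen <- screen
  sel <- screen$parameter[screen$significant]
  report$clinical_ari <- NA_real_
  if (length(sel) >= 2) {
    clin <- as.matrix(cohort[sel])
    rownames(clin) <- cohort$sample_id
    clin <- clin[, apply(clin, 2, function(v) !any(is.na(v))), drop = FALSE]
    if (ncol(clin) >= 2) {
      z <- zscore_normalize(clin)
      part_clin <- cut_tree(ward_linkage(dist(z)), k = nlevels(cohort$group))
      groups <- setNames(as.integer(cohort$group), cohort$sample_id)
      report$clinical_ari <- adjusted_rand_index(part_clin, groups)
    }
  }

  # proteomic component: Jaccard/Ward, high-BMI cluster pattern
  part <- cut_tree(ward_linkage(jaccard_dist_matrix(filtered)), k = config$k)
  hi <- high_bmi_cluster(part, cohort)
  report$pattern <- extract_discriminative_pattern(
    filtered, part, hi, alpha = config$alpha, cohort = cohort)

  # BMI prediction, all samples then with excluded groups removed
  y <- setNames(cohort$bmi, cohort$sample_id)
  report$stability_all <- stability_select(
    filtered, y[rownames(filtered)],
    iterations = config$iterations, fraction = config$fraction,
    folds = config$folds, repeats = config$repeats,
    seed = config$seed + 2000L)
  sub <- subset_samples(presence, cohort, config$exclude_groups)
  report$dim_subset <- dim(sub$matrix)
  report$stability_subset <- stability_select(
    sub$matrix, y[rownames(sub$matrix)],
    iterations = config$iterations, fraction = config$fraction,
    folds = config$folds, repeats = config$repeats,
    seed = config$seed + 3000L)

  if (!is.null(config$outdir)) write_pipeline_outputs(report, cohort,
                                                      presence, filtered)
  invisible(report)
}

write_pipeline_outputs <- function(report, cohort, presence, filtered) {
  dir <- report$config$outdir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_table(cohort, file.path(dir, "cohort.tsv"))
  write_presence_matrix(presence, file.path(dir, "presence_matrix.tsv"))
  write_presence_matrix(filtered, file.path(dir, "presence_filtered.tsv"))
  write.table(report$screen, file.path(dir, "parameter_screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$pattern$table, file.path(dir, "pattern.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c(
    "plasmapattern pipeline report",
    sprintf("seed: %d", report$config$seed),
    sprintf("catalog: %d proteins, %d core, %d after filter",
            report$catalog$n_total, report$catalog$n_core,
            report$catalog$n_after_filter),
    sprintf("filtered matrix: %d x %d", report$dim_filtered[1],
            report$dim_filtered[2]),
    sprintf("clinical clustering vs BMI groups: ARI = %.3f",
            report$clinical_ari),
    sprintf("high-BMI cluster pattern: %d proteins (mean BMI %.1f vs %.1f, p = %.4g)",
            length(report$pattern$pattern), report$pattern$bmi$mean_in,
            report$pattern$bmi$mean_out, report$pattern$bmi$p_value),
    sprintf("consensus (all samples): %d proteins; MAE holdout %.2f, in-sample %.2f",
            length(report$stability_all$consensus),
            report$stability_all$mae["holdout_pooled"],
            report$stability_all$mae["refit_insample"]),
    sprintf("consensus (%s removed): %d proteins; MAE holdout %.2f, in-sample %.2f",
            paste(report$config$exclude_groups, collapse = "+"),
            length(report$stability_subset$consensus),
            report$stability_subset$mae["holdout_pooled"],
            report$stability_subset$mae["refit_insample"]))
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(dir)
}
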