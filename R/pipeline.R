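#' Pipeline stages
#'
#' Thin orchestration over the package's functions, writing the standard
#' artifacts of each analysis stage to an output directory. Every stage is
#' deterministic given its inputs and seed; each writes a short log of counts
#' in/out and exclusion tallies.
#'
#' * `run_simulate()` — simulate a dataset ([generate_dataset()]).
#' * `run_analyze()` — read tracks, label cells, write the cell table,
#'   motility metrics, kinetics tables and colony calls.
#' * `run_fit()` — build the division-event table, fit the generation-
#'   dependent outcome model, write parameters (YAML) and per-generation
#'   predictions (TSV).
#' * `run_cluster()` — behavioral phenotype clustering and enrichment table.
#' * `run_compare()` — condition comparison of metric tables.
#'
#' @param config a [synthetic_config()] (`run_simulate`).
#' @param out_dir output directory.
#' @return named vector of written paths, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config, out_dir) {
  generate_dataset(config, out_dir, overwrite = TRUE)
}

#' @rdname pipeline
#' @param tracks,lineage input track TSV and optional CTC lineage file.
#' @param root_type,condition tree metadata (see [read_tracks()]).
#' @param include_censored censoring-inclusion flag for death rates.
#' @export
run_analyze <- function(tracks, lineage = NULL, out_dir,
                        root_type = "MEP", condition = "control",
                        include_censored = FALSE) {
  trees <- read_tracks(tracks, lineage, root_type = root_type,
                       condition = condition)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- cell_table(trees)
  metrics <- motility_metrics(trees)
  outcome_tab <- division_outcome_table(trees)
  eff <- colony_efficiency(trees)
  commit <- commitment_frequency(trees)
  states <- setdiff(unique(cells$state), "indeterminate")
  death <- do.call(rbind, lapply(states, function(s) {
    d <- death_rate_by_state(trees, s, include_censored = include_censored)
    if (nrow(d)) cbind(state = s, d)
  }))
  files <- c(cells = file.path(out_dir, "cells.tsv"),
             metrics = file.path(out_dir, "metrics.tsv"),
             outcomes = file.path(out_dir, "division_outcomes.tsv"),
             death = file.path(out_dir, "death_rates.tsv"),
             colonies = file.path(out_dir, "colonies.tsv"),
             log = file.path(out_dir, "analyze_log.yaml"))
  write_tsv_table(cells, files[["cells"]])
  write_tsv_table(metrics, files[["metrics"]])
  write_tsv_table(outcome_tab, files[["outcomes"]])
  if (!is.null(death)) write_tsv_table(death, files[["death"]])
  write_tsv_table(data.frame(colony = vapply(trees, function(t) t$root_id,
                                             character(1)),
                             call = eff$calls),
                  files[["colonies"]])
  yaml::write_yaml(list(
    n_trees = length(trees), n_cells = nrow(cells),
    excluded_divisions = attr(outcome_tab, "excluded"),
    forming_efficiency = eff$forming_efficiency,
    death_frequency = eff$death_frequency,
    commitment_frac_E = commit$frac_E), files[["log"]])
  invisible(files)
}

#' @rdname pipeline
#' @param trees list of [lineage_tree()] (or `tracks` path as above).
#' @param shared,generations,ci options of [mep_markov()] /
#'   [predict.mep_markov()].
#' @param seed seed for bootstrap intervals.
#' @export
run_fit <- function(trees = NULL, tracks = NULL, out_dir,
                    shared = FALSE, generations = 1:13,
                    ci = c("delta", "bootstrap"), seed = 1L) {
  ci <- match.arg(ci)
  if (is.null(trees)) trees <- read_tracks(tracks)
  events <- division_events(trees)
  fit <- mep_markov(events, shared = shared)
  pred <- predict(fit, generations = generations, interval = ci, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(params = file.path(out_dir, "markov_params.yaml"),
             predictions = file.path(out_dir, "predictions.tsv"))
  write_mep_markov(fit, files[["params"]])
  write_tsv_table(pred, files[["predictions"]])
  invisible(structure(files, fit = fit))
}

#' @rdname pipeline
#' @param metrics metrics table from [motility_metrics()] (or read from a
#'   previous `run_analyze` output).
#' @param k fixed cluster count; selected by silhouette when `NULL`.
#' @export
run_cluster <- function(metrics, out_dir, k = NULL, seed = 1L) {
  # indeterminate and censored cells carry no usable phenotype
  metrics <- metrics[metrics$state != "indeterminate" & !metrics$censored, ,
                     drop = FALSE]
  rep <- cluster_phenotypes(metrics, k = k, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(enrichment = file.path(out_dir, "enrichment.tsv"),
             scores = file.path(out_dir, "pca_scores.tsv"),
             loadings = file.path(out_dir, "pca_loadings.tsv"))
  enr <- data.frame(state = rownames(rep$enrichment$counts),
                    rep$enrichment$counts,
                    round(rep$enrichment$percent, 2),
                    predominant = rep$enrichment$predominant,
                    check.names = FALSE)
  names(enr) <- c("state",
                  paste0("n_cluster", colnames(rep$enrichment$counts)),
                  paste0("pct_cluster", colnames(rep$enrichment$percent)),
                  "predominant")
  write_tsv_table(enr, files[["enrichment"]])
  write_tsv_table(data.frame(cell_id = attr(rep$features, "cell_ids"),
                             state = attr(rep$features, "states"),
                             cluster = rep$assignments,
                             rep$pca$scores, check.names = FALSE),
                  files[["scores"]])
  write_tsv_table(data.frame(feature = rownames(rep$pca$loadings),
                             rep$pca$loadings, check.names = FALSE),
                  files[["loadings"]])
  invisible(structure(files, report = rep))
}

#' @rdname pipeline
#' @param metric_cols metric columns to compare across conditions.
#' @param adjust p-value adjustment (see [compare_conditions()]).
#' @export
run_compare <- function(metrics, out_dir,
                        metric_cols = c("lifespan", "total_distance",
                                        "diffusion_distance",
                                        "peak_velocity"),
                        adjust = "none") {
  res <- compare_conditions(metrics, metric_cols, adjust = adjust)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  file <- file.path(out_dir, "condition_comparison.tsv")
  write_tsv_table(res, file)
  invisible(structure(c(comparison = file), table = res))
}
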