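#' Per-generation death rate for one cell state
#'
#' For each generation, the fraction of cells of the given fate label that
#' died, among resolved cells of that label present at that generation.
#' Censored cells (`lost`, `movie_end`) are excluded from numerator and
#' denominator unless `include_censored` (they can never contribute deaths
#' either way). Generations with an empty denominator are omitted.
#'
#' @param trees a `lineage_tree` or list of them.
#' @param state fate label to tabulate (e.g. `"E_destined"`).
#' @param include_censored keep censored cells in the denominator.
#' @param per_movie return one rate per (colony, generation) instead of
#'   pooling all colonies.
#' @return data frame with columns `generation`, `deaths`, `cells`, `rate`
#'   (plus `colony` when `per_movie`).
#' @export
death_rate_by_state <- function(trees, state, include_censored = FALSE,
                                per_movie = FALSE) {
  cells <- cell_table(trees)
  cells <- cells[cells$state == state, , drop = FALSE]
  if (!include_censored)
    cells <- cells[!cells$end_event %in% c("lost", "movie_end"), , drop = FALSE]
  if (nrow(cells) == 0L)
    return(data.frame(generation = integer(), deaths = integer(),
                      cells = integer(), rate = numeric()))
  key <- if (per_movie) list(colony = cells$colony,
                             generation = cells$generation)
         else list(generation = cells$generation)
  agg <- stats::aggregate(cbind(deaths = cells$end_event == "died",
                                cells = rep(1L, nrow(cells))), key, sum)
  agg$rate <- agg$deaths / agg$cells
  agg[order(agg$generation), , drop = FALSE]
}

#' Cell counts per generation and state
#'
#' The expansion-curve table: number of cells of each fate label at each
#' generation, per colony and averaged across colonies (mean and SD over
#' colonies).
#'
#' @param trees a `lineage_tree` or list of them.
#' @return list with `per_colony` (colony x generation x state counts, long
#'   format) and `summary` (generation, state, mean, sd over colonies).
#' @export
expansion_by_generation <- function(trees) {
  cells <- cell_table(trees)
  per <- stats::aggregate(list(cells = rep(1L, nrow(cells))),
                          list(colony = cells$colony,
                               generation = cells$generation,
                               state = cells$state), sum)
  # missing (colony, generation, state) combinations are true zero counts
  colonies <- unique(per$colony)
  grid <- expand.grid(colony = colonies,
                      generation = sort(unique(per$generation)),
                      state = unique(per$state),
                      stringsAsFactors = FALSE)
  per <- merge(grid, per, all.x = TRUE)
  per$cells[is.na(per$cells)] <- 0L
  sm <- stats::aggregate(list(mean = per$cells),
                         list(generation = per$generation, state = per$state),
                         mean)
  sdv <- stats::aggregate(list(sd = per$cells),
                          list(generation = per$generation, state = per$state),
                          stats::sd)
  summary <- merge(sm, sdv)
  summary <- summary[order(summary$state, summary$generation), , drop = FALSE]
  rownames(summary) <- NULL
  list(per_colony = per, summary = summary)
}

#' Division-outcome counts by generation
#'
#' Absolute numbers of bipotent (MEP) division outcomes — expansion,
#' maintenance toward E, maintenance toward Mk, exhaustion — per generation,
#' with totals and the exclusion tally (divisions involving indeterminate
#' cells) carried through.
#'
#' @param trees a `lineage_tree` or list of them.
#' @return data frame `generation` x outcome counts with a `total` column;
#'   attribute `"excluded"` holds the exclusion count.
#' @export
division_outcome_table <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  excluded <- 0L
  evs <- do.call(rbind, lapply(trees, function(tree) {
    ev <- classify_divisions(tree)
    excluded <<- excluded + attr(ev, "excluded")
    ev
  }))
  outcomes <- c("expansion", "maintenance_E", "maintenance_Mk", "exhaustion")
  evs <- evs[evs$outcome %in% outcomes, , drop = FALSE]
  gens <- if (nrow(evs)) seq_len(max(evs$generation)) else integer()
  tab <- table(factor(evs$generation, levels = gens),
               factor(evs$outcome, levels = outcomes))
  res <- data.frame(generation = gens, unclass(as.matrix(tab)),
                    check.names = FALSE)
  rownames(res) <- NULL
  res$total <- rowSums(res[outcomes])
  attr(res, "excluded") <- excluded
  res
}

#' Lineage-commitment frequency
#'
#' Of all committed daughters produced by bipotent divisions (maintenance and
#' exhaustion daughters), the fraction destined to the E versus Mk lineage.
#'
#' @param trees a `lineage_tree` or list of them.
#' @return list with `n_E`, `n_Mk`, `frac_E`, `frac_Mk`; fractions are `NaN`
#'   (flagged by `defined = FALSE`) when no committed daughter was observed.
#' @export
commitment_frequency <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  n_E <- 0L; n_Mk <- 0L
  for (tree in trees) {
    labels <- assign_fate_labels(tree)
    ev <- classify_divisions(tree, labels)
    for (i in seq_len(nrow(ev))) {
      if (!ev$outcome[i] %in% c("maintenance_E", "maintenance_Mk",
                                "exhaustion")) next
      kids <- tree$cells[[ev$parent_id[i]]]$children
      lk <- labels[kids]
      n_E <- n_E + sum(lk == "E_destined")
      n_Mk <- n_Mk + sum(lk == "Mk_destined")
    }
  }
  tot <- n_E + n_Mk
  list(n_E = n_E, n_Mk = n_Mk,
       frac_E = if (tot) n_E / tot else NaN,
       frac_Mk = if (tot) n_Mk / tot else NaN,
       defined = tot > 0L)
}

#' Classify the colony type of a tree
#'
#' Based on marker-resolved leaves: both lineages present is an Mk/E mixed
#' colony; only E (CD71bright or CD235a leaves) is E-only; only Mk (CD41 or
#' endomitosis) is Mk-only; no surviving marker-resolved progeny is
#' `no_colony`.
#'
#' @param tree a [lineage_tree()].
#' @param labels optional labels (unused beyond leaf evidence; accepted for
#'   interface symmetry).
#' @return one of `"MkE_mixed"`, `"E_only"`, `"Mk_only"`, `"no_colony"`.
#' @export
classify_colony <- function(tree, labels = NULL) {
  leaves <- tree_leaves(tree)
  has_e <- FALSE; has_mk <- FALSE
  for (id in leaves) {
    c <- tree$cells[[id]]
    if ("CD41" %in% c$markers || c$end_event == "endomitosis") has_mk <- TRUE
    if (any(c("CD71bright", "CD235a") %in% c$markers)) has_e <- TRUE
  }
  if (has_e && has_mk) "MkE_mixed"
  else if (has_e) "E_only"
  else if (has_mk) "Mk_only"
  else "no_colony"
}

#' Colony-forming efficiency and root death frequency
#'
#' `forming_efficiency` is the fraction of plated cells that gave rise to a
#' scoreable colony (call other than `no_colony`); `death_frequency` is the
#' fraction of plated cells that died before producing progeny. The two need
#' not sum to one: roots can be lost to tracking.
#'
#' @param trees list of [lineage_tree()].
#' @return list with `n_roots`, `forming_efficiency`, `death_frequency` and
#'   the vector of colony `calls`.
#' @export
colony_efficiency <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  calls <- vapply(trees, classify_colony, character(1))
  died_pre <- vapply(trees, function(tree) {
    root <- tree$cells[[tree$root_id]]
    root$end_event == "died" && length(root$children) == 0L
  }, logical(1))
  list(n_roots = length(trees),
       forming_efficiency = mean(calls != "no_colony"),
       death_frequency = mean(died_pre),
       calls = calls)
}

#' Compare a metric table across conditions
#'
#' For each requested metric column: group means and SDs, then a two-sided
#' Welch t-test (two groups) or one-way ANOVA (three or more). P-values are
#' unadjusted by default; `adjust = "BH"` applies Benjamini-Hochberg across
#' metrics.
#'
#' @param metrics data frame (e.g. from [motility_metrics()]).
#' @param metric_cols character vector of numeric columns to compare.
#' @param group_col grouping column, default `"condition"`.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return data frame with one row per metric: per-group `mean_*`/`sd_*`/
#'   `n_*` columns, `statistic`, `df`, `p` (and `p_adj` when adjusted).
#'   Metrics with any group of fewer than 2 complete observations are
#'   skipped with a warning.
#' @export
compare_conditions <- function(metrics, metric_cols, group_col = "condition",
                               adjust = "none") {
  g <- factor(metrics[[group_col]])
  if (nlevels(g) < 2L) stop("need at least 2 groups in '", group_col, "'")
  rows <- list()
  for (m in metric_cols) {
    x <- metrics[[m]]
    ok <- is.finite(x)
    ns <- tapply(ok, g, sum)
    if (any(ns < 2L)) {
      warning("metric '", m, "' skipped: group with fewer than 2 observations")
      next
    }
    xs <- x[ok]; gs <- droplevels(g[ok])
    means <- tapply(xs, gs, mean); sds <- tapply(xs, gs, stats::sd)
    if (nlevels(gs) == 2L) {
      tt <- stats::t.test(xs ~ gs)
      stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
      method <- "t"
    } else {
      fit <- stats::aov(xs ~ gs)
      an <- summary(fit)[[1L]]
      stat <- an[["F value"]][1L]; df <- an[["Df"]][1L]; p <- an[["Pr(>F)"]][1L]
      method <- "anova"
    }
    row <- data.frame(metric = m, method = method, statistic = stat,
                      df = df, p = p, stringsAsFactors = FALSE)
    for (lev in levels(gs)) {
      row[[paste0("mean_", lev)]] <- unname(means[lev])
      row[[paste0("sd_", lev)]] <- unname(sds[lev])
      row[[paste0("n_", lev)]] <- unname(sum(gs == lev))
    }
    rows[[m]] <- row
  }
  res <- do.call(rbind, rows)
  if (!is.null(res)) {
    rownames(res) <- NULL
    if (adjust != "none") res$p_adj <- stats::p.adjust(res$p, method = adjust)
  }
  res
}

#' Per-cell summary table
#'
#' One row per cell across trees: colony, generation, inferred fate label,
#' birth/end times, end event and censoring flag. The workhorse input of the
#' kinetics tabulations.
#'
#' @param trees a `lineage_tree` or list of them.
#' @return data frame.
#' @export
cell_table <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  res <- do.call(rbind, lapply(trees, function(tree) {
    labels <- assign_fate_labels(tree)
    gen <- generation_index(tree)
    do.call(rbind, lapply(tree$cells, function(c) {
      data.frame(colony = tree$root_id, cell_id = c$cell_id,
                 parent_id = c$parent_id,
                 generation = unname(gen[c$cell_id]),
                 state = unname(labels[c$cell_id]),
                 condition = tree$condition,
                 birth_time = c$birth_time, end_time = c$end_time,
                 end_event = c$end_event,
                 censored = c$end_event %in% c("lost", "movie_end"),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL
  res
}
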