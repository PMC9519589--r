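#' Per-cell motility and lifespan metrics
#'
#' Behavioral phenotype metrics computed from a cell's (x, y) trajectory over
#' its lifetime, following the conventions of time-lapse colony tracking:
#'
#' * `total_distance()` — sum of Euclidean step lengths between consecutive
#'   frames (micrometres).
#' * `diffusion_distance()` — straight-line distance between the first and
#'   last recorded positions.
#' * `directionality()` — total distance over diffusion distance
#'   (dimensionless, >= 1); `NaN` when the net displacement is zero.
#' * `peak_velocity()` — the largest per-interval displacement divided by
#'   that interval's actual duration (micrometres/hour). Frame intervals are
#'   non-uniform by design, so each pair's true time difference is used.
#'
#' @param trajectory data frame with columns `x`, `y` and (for
#'   `peak_velocity`) `time` in hours, ordered by frame.
#' @return a single numeric value.
#' @name motility-metrics
NULL

#' @rdname motility-metrics
#' @export
total_distance <- function(trajectory) {
  if (nrow(trajectory) < 2L) return(0)
  sum(sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2))
}

#' @rdname motility-metrics
#' @export
diffusion_distance <- function(trajectory) {
  n <- nrow(trajectory)
  if (n < 2L) return(0)
  sqrt((trajectory$x[n] - trajectory$x[1L])^2 +
       (trajectory$y[n] - trajectory$y[1L])^2)
}

#' @rdname motility-metrics
#' @export
directionality <- function(trajectory) {
  dd <- diffusion_distance(trajectory)
  if (dd == 0) return(NaN)
  total_distance(trajectory) / dd
}

#' @rdname motility-metrics
#' @export
peak_velocity <- function(trajectory) {
  if (nrow(trajectory) < 2L) return(0)
  dt <- diff(trajectory$time)
  if (any(dt <= 0)) stop("non-positive time step in trajectory")
  max(sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2) / dt)
}

#' Lifespan of a cell
#'
#' Time between birth (division of the parent; plating for the root, 0 h) and
#' the cell's endpoint, in hours. For cells censored by track loss or movie
#' end this is a lower bound on the true lifespan.
#'
#' @param cell a cell record from a [lineage_tree()].
#' @return hours, with attribute `"censored"`.
#' @export
lifespan <- function(cell) {
  out <- cell$end_time - cell$birth_time
  attr(out, "censored") <- cell$end_event %in% c("lost", "movie_end")
  out
}

#' Motility/lifespan feature table for a set of trees
#'
#' One row per cell with its colony, inferred fate label (`state`),
#' condition, generation, and all motility metrics. Undefined directionality
#' (zero net displacement) is kept as `NaN` here; downstream feature builders
#' exclude and count those rows.
#'
#' @param trees a `lineage_tree` or list of them.
#' @param labels optional list of per-tree label vectors (computed if
#'   missing).
#' @return data frame.
#' @export
motility_metrics <- function(trees, labels = NULL) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  if (!is.null(labels) && !is.list(labels)) labels <- list(labels)
  blocks <- lapply(seq_along(trees), function(i) {
    tree <- trees[[i]]
    lab <- if (is.null(labels)) assign_fate_labels(tree) else labels[[i]]
    gen <- generation_index(tree)
    do.call(rbind, lapply(tree$cells, function(c) {
      ls <- lifespan(c)
      data.frame(colony = tree$root_id, cell_id = c$cell_id,
                 state = unname(lab[c$cell_id]),
                 condition = tree$condition,
                 generation = unname(gen[c$cell_id]),
                 lifespan = as.numeric(ls),
                 censored = attr(ls, "censored"),
                 total_distance = total_distance(c$trajectory),
                 diffusion_distance = diffusion_distance(c$trajectory),
                 directionality = directionality(c$trajectory),
                 peak_velocity = peak_velocity(c$trajectory),
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  res
}

#' Write a metrics table as TSV
#' @param metrics data frame from [motility_metrics()] or any table.
#' @param file output path.
#' @export
write_tsv_table <- function(metrics, file) {
  utils::write.table(metrics, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}
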