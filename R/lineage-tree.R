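#' Construct a lineage tree
#'
#' A `lineage_tree` is the rooted binary-division tree of all tracked progeny
#' of one plated progenitor (one colony). Cells are stored as records keyed by
#' cell id; each record carries birth/end times in hours since plating, the
#' endpoint event, endpoint lineage-marker calls, parent/child links and the
#' per-frame (x, y) trajectory in micrometres.
#'
#' @param cells named list of cell records as produced by [cell_record()];
#'   names must equal the records' `cell_id`s.
#' @param root_type sorted identity of the plated cell: `"MEP"`, `"MkP"` or
#'   `"ErP"`. Metadata from the sort, not a labeling constraint.
#' @param condition culture condition: `"control"`, `"noTPO"` or `"noEPO"`.
#' @param validate check structural invariants (acyclicity, resolvable
#'   parents, binary divisions, child birth after parent end).
#' @return an object of class `lineage_tree`.
#' @seealso [read_tracks()], [assign_fate_labels()], [generation_index()]
#' @export
lineage_tree <- function(cells, root_type = c("MEP", "MkP", "ErP"),
                         condition = c("control", "noTPO", "noEPO"),
                         validate = TRUE) {
  root_type <- match.arg(root_type)
  condition <- match.arg(condition)
  stopifnot(is.list(cells), length(cells) >= 1L)
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  if (is.null(names(cells))) names(cells) <- ids
  if (!identical(unname(names(cells)), unname(ids)))
    stop("names(cells) must equal the cell_id fields")
  roots <- unname(ids[vapply(cells, function(c) is.na(c$parent_id),
                             logical(1))])
  if (length(roots) != 1L)
    stop("a lineage tree must have exactly one root, found ", length(roots))
  tree <- structure(
    list(root_id = roots, cells = cells,
         root_type = root_type, condition = condition),
    class = "lineage_tree")
  if (validate) validate_lineage_tree(tree)
  tree
}

#' Create a single cell record
#'
#' @param cell_id,parent_id identifiers; `parent_id = NA` marks the root.
#' @param birth_time,end_time hours since plating.
#' @param end_event one of `"divided"`, `"died"`, `"endomitosis"`, `"lost"`,
#'   `"movie_end"`.
#' @param markers character vector, subset of
#'   `c("CD41", "CD71bright", "CD235a")`, observed on this cell at endpoint.
#' @param trajectory data frame with columns `frame`, `time`, `x`, `y`,
#'   ordered by frame; `time` in hours, positions in micrometres.
#' @param children character vector of daughter ids (filled by tree builders).
#' @return a plain list with class-free fields, consumed by [lineage_tree()].
#' @export
cell_record <- function(cell_id, parent_id = NA_character_,
                        birth_time = 0, end_time = birth_time,
                        end_event = c("divided", "died", "endomitosis",
                                      "lost", "movie_end"),
                        markers = character(),
                        trajectory = NULL,
                        children = character()) {
  end_event <- match.arg(end_event)
  if (end_time < birth_time) stop("end_time < birth_time for cell ", cell_id)
  bad <- setdiff(markers, c("CD41", "CD71bright", "CD235a"))
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  if (is.null(trajectory))
    trajectory <- data.frame(frame = 0L, time = birth_time, x = 0, y = 0)
  list(cell_id = as.character(cell_id),
       parent_id = as.character(parent_id),
       birth_time = birth_time, end_time = end_time,
       end_event = end_event, markers = markers,
       trajectory = trajectory, children = as.character(children))
}

#' @export
print.lineage_tree <- function(x, ...) {
  gi <- generation_index(x)
  cat("<lineage_tree> ", length(x$cells), " cells, root ", x$root_id,
      " (", x$root_type, ", ", x$condition, "), max generation ",
      max(gi), "\n", sep = "")
  ev <- table(vapply(x$cells, function(c) c$end_event, character(1)))
  cat("  end events:", paste(names(ev), ev, sep = "=", collapse = " "), "\n")
  invisible(x)
}

validate_lineage_tree <- function(tree) {
  cells <- tree$cells
  ids <- names(cells)
  for (c in cells) {
    if (!is.na(c$parent_id) && !c$parent_id %in% ids)
      stop("unresolvable parent_id '", c$parent_id, "' for cell ", c$cell_id)
    if (length(c$children) > 2L)
      stop("cell ", c$cell_id, " has ", length(c$children), " children (> 2)")
    if ((c$end_event == "divided") != (length(c$children) == 2L))
      stop("cell ", c$cell_id,
           ": end_event 'divided' must coincide with exactly 2 children")
    if (c$end_time < c$birth_time)
      stop("cell ", c$cell_id, ": end_time < birth_time")
    for (k in c$children) {
      if (cells[[k]]$birth_time < c$end_time - 1e-9)
        stop("child ", k, " born before parent ", c$cell_id, " ended")
    }
    tr <- c$trajectory
    if (nrow(tr) > 1L) {
      if (any(diff(tr$frame) <= 0))
        stop("cell ", c$cell_id, ": frames not strictly increasing")
      if (any(diff(tr$time) <= 0))
        stop("cell ", c$cell_id, ": times not strictly increasing")
    }
  }
  # acyclicity / connectivity: walking up from every cell must reach the root
  for (id in ids) {
    seen <- character()
    cur <- id
    while (!is.na(cells[[cur]]$parent_id)) {
      if (cur %in% seen) stop("cycle detected at cell ", cur)
      seen <- c(seen, cur)
      cur <- cells[[cur]]$parent_id
    }
    if (cur != tree$root_id) stop("cell ", id, " not connected to root")
  }
  invisible(tree)
}

#' Generation index of every cell
#'
#' The plated cell is generation 1; each daughter is its parent's generation
#' plus one. A division is indexed by the generation of the dividing cell.
#'
#' @param tree a [lineage_tree()].
#' @return named integer vector, one entry per cell.
#' @export
generation_index <- function(tree) {
  gen <- stats::setNames(integer(length(tree$cells)), names(tree$cells))
  gen[tree$root_id] <- 1L
  queue <- tree$root_id
  while (length(queue)) {
    id <- queue[1L]; queue <- queue[-1L]
    kids <- tree$cells[[id]]$children
    if (length(kids)) {
      gen[kids] <- gen[id] + 1L
      queue <- c(queue, kids)
    }
  }
  gen
}

#' Leaf cells of a lineage tree
#' @param tree a [lineage_tree()].
#' @return character vector of ids of cells without children.
#' @export
tree_leaves <- function(tree) {
  names(tree$cells)[vapply(tree$cells, function(c) length(c$children) == 0L,
                           logical(1))]
}

# post-order id sequence (children before parents)
postorder_ids <- function(tree) {
  out <- character(0)
  walk <- function(id) {
    for (k in tree$cells[[id]]$children) walk(k)
    out[[length(out) + 1L]] <<- id
  }
  walk(tree$root_id)
  unlist(out)
}
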