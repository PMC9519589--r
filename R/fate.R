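#' Infer fate labels by back-propagating terminal lineage identity
#'
#' Leaves are identified from endpoint evidence: `CD41` marks the
#' megakaryocytic (Mk) lineage, `CD71bright` or `CD235a` the erythroid (E)
#' lineage, and endomitosis is terminal Mk maturation (counted as Mk even
#' without a marker call). Each internal cell is then labeled by the lineages
#' among its identified descendant leaves: both lineages present means the
#' cell was upstream of both Mk and E daughters (`bipotent`); only Mk means
#' `Mk_destined`; only E means `E_destined`; no identified leaf below
#' (progeny lost or dead before marker onset) means `indeterminate`.
#'
#' In trees grown from sorted unipotent progenitors (`root_type` `"ErP"` or
#' `"MkP"`) every resolvable cell is labeled `committed_ErP` /
#' `committed_MkP`. A cell carrying both an Mk and an E marker is ambiguous:
#' it is labeled `indeterminate` and reported via the `"ambiguous"`
#' attribute (and a single message), never dropped silently.
#'
#' @param tree a [lineage_tree()].
#' @return named character vector of labels, one per cell, with attribute
#'   `"ambiguous"` listing double-positive cell ids.
#' @export
assign_fate_labels <- function(tree) {
  cells <- tree$cells
  ids <- names(cells)
  ambiguous <- character()

  leaf_lineage <- function(c) {
    has_mk <- "CD41" %in% c$markers || c$end_event == "endomitosis"
    has_e <- any(c("CD71bright", "CD235a") %in% c$markers)
    if ("CD41" %in% c$markers && has_e) {
      ambiguous <<- c(ambiguous, c$cell_id)
      return(character())
    }
    if (has_mk) "Mk" else if (has_e) "E" else character()
  }

  # lineage sets propagate bottom-up
  lin <- stats::setNames(vector("list", length(ids)), ids)
  for (id in postorder_ids(tree)) {
    c <- cells[[id]]
    lin[[id]] <- if (length(c$children) == 0L) leaf_lineage(c)
                 else unique(unlist(lin[c$children]))
  }

  labels <- vapply(lin, function(s) {
    if (length(s) == 2L) "bipotent"
    else if (identical(s, "E")) "E_destined"
    else if (identical(s, "Mk")) "Mk_destined"
    else "indeterminate"
  }, character(1))

  if (tree$root_type %in% c("ErP", "MkP")) {
    committed <- if (tree$root_type == "ErP") "committed_ErP" else "committed_MkP"
    labels[labels != "indeterminate"] <- committed
  }
  if (length(ambiguous))
    message("assign_fate_labels: ", length(ambiguous),
            " ambiguous double-positive cell(s) labeled indeterminate")
  attr(labels, "ambiguous") <- ambiguous
  labels
}

#' Classify division outcomes of bipotent cells
#'
#' Each division by a `bipotent` parent is classified from its daughters'
#' fate labels: two bipotent daughters is an `expansion` (symmetric
#' self-renewal); one bipotent plus one E- or Mk-destined daughter is
#' `maintenance_E` / `maintenance_Mk` (asymmetric self-renewal); no bipotent
#' daughter is `exhaustion` (loss of bipotency, the absorbing outcome).
#' Divisions by non-bipotent parents are reported as `non_MEP`. Divisions
#' involving an `indeterminate` cell cannot be classified and are excluded,
#' with the count carried in the `"excluded"` attribute.
#'
#' @param tree a [lineage_tree()].
#' @param labels labels from [assign_fate_labels()]; computed if missing.
#' @return data frame with columns `parent_id`, `generation`,
#'   `division_time`, `outcome`, plus attributes `"excluded"` (count) and
#'   `"excluded_ids"`.
#' @export
classify_divisions <- function(tree, labels = NULL) {
  if (is.null(labels)) labels <- assign_fate_labels(tree)
  gen <- generation_index(tree)
  dividing <- names(tree$cells)[vapply(tree$cells,
                                       function(c) length(c$children) == 2L,
                                       logical(1))]
  out <- character(); pid <- character(); g <- integer(); tm <- numeric()
  excluded_ids <- character()
  is_committed_leafish <- function(lab, side)
    lab %in% paste0(side, "_destined") ||
      lab %in% paste0("committed_", c("ErP", "MkP"))

  for (id in dividing) {
    kids <- tree$cells[[id]]$children
    lp <- labels[[id]]
    lk <- unname(labels[kids])
    if (lp == "indeterminate" || any(lk == "indeterminate")) {
      excluded_ids <- c(excluded_ids, id)
      next
    }
    o <- if (lp != "bipotent") "non_MEP" else {
      nb <- sum(lk == "bipotent")
      if (nb == 2L) "expansion"
      else if (nb == 1L) {
        other <- lk[lk != "bipotent"][1L]
        if (grepl("E", other) && !grepl("Mk", other)) "maintenance_E"
        else "maintenance_Mk"
      } else "exhaustion"
    }
    pid <- c(pid, id); g <- c(g, gen[[id]])
    tm <- c(tm, tree$cells[[id]]$end_time); out <- c(out, o)
  }
  res <- data.frame(parent_id = pid, generation = g, division_time = tm,
                    outcome = out, stringsAsFactors = FALSE)
  res <- res[order(res$generation, res$division_time, res$parent_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- length(excluded_ids)
  attr(res, "excluded_ids") <- excluded_ids
  res
}

#' Extract root-to-terminal division-outcome sequences
#'
#' Follows every path from the plated cell through bipotent cells, recording
#' the classified outcome of each division along the way. A path ends at an
#' exhaustion division, at the death of a bipotent cell, or at censoring
#' (movie end / lost track / unclassifiable division). Expansion divisions
#' branch the path in two, so the returned sequences can share prefixes.
#'
#' @param tree a [lineage_tree()].
#' @param labels labels from [assign_fate_labels()]; computed if missing.
#' @return list of data frames (`generation`, `outcome`), each with
#'   attributes `"censored"` (`TRUE` unless the path ends in exhaustion) and
#'   `"end_reason"` (`"exhaustion"`, `"died"`, `"movie_end"`, `"lost"`,
#'   `"endomitosis"` or `"unclassified"`).
#' @export
extract_division_sequences <- function(tree, labels = NULL) {
  if (is.null(labels)) labels <- assign_fate_labels(tree)
  gen <- generation_index(tree)
  ev <- classify_divisions(tree, labels)
  outcome_of <- stats::setNames(ev$outcome, ev$parent_id)

  seqs <- list()
  emit <- function(path_g, path_o, reason) {
    s <- data.frame(generation = as.integer(path_g), outcome = path_o,
                    stringsAsFactors = FALSE)
    attr(s, "censored") <- !identical(reason, "exhaustion")
    attr(s, "end_reason") <- reason
    seqs[[length(seqs) + 1L]] <<- s
  }
  walk <- function(id, path_g, path_o) {
    c <- tree$cells[[id]]
    if (length(c$children) == 0L) {
      emit(path_g, path_o, c$end_event)
      return(invisible())
    }
    o <- outcome_of[id]
    if (is.na(o) || o == "non_MEP") {
      emit(path_g, path_o, "unclassified")
      return(invisible())
    }
    path_g <- c(path_g, gen[[id]]); path_o <- c(path_o, o)
    if (o == "exhaustion") {
      emit(path_g, path_o, "exhaustion")
    } else {
      next_bipotent <- c$children[labels[c$children] == "bipotent"]
      for (k in next_bipotent) walk(k, path_g, path_o)
    }
    invisible()
  }
  root_lab <- labels[[tree$root_id]]
  if (root_lab %in% c("bipotent", "E_destined", "Mk_destined") &&
      tree$root_type == "MEP") {
    if (root_lab == "bipotent") {
      walk(tree$root_id, integer(), character())
    } else {
      # root never visibly produced both lineages (single-lineage colony):
      # no division along the path is classifiable as an MEP outcome
      root <- tree$cells[[tree$root_id]]
      emit(integer(), character(),
           if (length(root$children)) "unclassified" else root$end_event)
    }
  } else if (root_lab == "indeterminate") {
    emit(integer(), character(), tree$cells[[tree$root_id]]$end_event)
  }
  seqs
}

#' Division-event table for outcome modeling
#'
#' Flattens classified divisions of one or more trees into the observation
#' unit of the generation-dependent outcome model: one row per bipotent
#' division with its `from_state` (the outcome of the division that created
#' the dividing cell, `"start"` for the plated cell), `generation` and
#' `outcome`. Divisions whose from-state is unclassifiable are dropped and
#' tallied in the `"dropped"` attribute.
#'
#' @param trees a `lineage_tree` or list of them.
#' @return data frame with columns `colony`, `from_state`, `generation`,
#'   `outcome`.
#' @export
division_events <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  dropped <- 0L
  blocks <- lapply(trees, function(tree) {
    labels <- assign_fate_labels(tree)
    ev <- classify_divisions(tree, labels)
    ev <- ev[ev$outcome != "non_MEP", , drop = FALSE]
    if (nrow(ev) == 0L) return(NULL)
    outcome_of <- stats::setNames(ev$outcome, ev$parent_id)
    from <- vapply(ev$parent_id, function(id) {
      pid <- tree$cells[[id]]$parent_id
      if (is.na(pid)) "start"
      else if (!is.na(outcome_of[pid])) unname(outcome_of[pid])
      else NA_character_
    }, character(1), USE.NAMES = FALSE)
    keep <- !is.na(from)
    dropped <<- dropped + sum(!keep)
    if (!any(keep)) return(NULL)
    data.frame(colony = tree$root_id, from_state = from[keep],
               generation = ev$generation[keep], outcome = ev$outcome[keep],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, blocks)
  if (is.null(res))
    res <- data.frame(colony = character(), from_state = character(),
                      generation = integer(), outcome = character())
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Which cells have a fully marker-resolved subtree?
#'
#' A cell is fully resolved when every leaf below it (including itself if it
#' is a leaf) carries lineage evidence: a marker call or endomitosis. Label
#' inference is exact on these cells; elsewhere it degrades gracefully to
#' `indeterminate` or partial calls.
#'
#' @param tree a [lineage_tree()].
#' @return named logical vector over cells.
#' @export
fully_resolved_cells <- function(tree) {
  res <- stats::setNames(logical(length(tree$cells)), names(tree$cells))
  for (id in postorder_ids(tree)) {
    c <- tree$cells[[id]]
    res[[id]] <- if (length(c$children) == 0L)
      length(c$markers) > 0L || c$end_event == "endomitosis"
    else all(res[c$children])
  }
  res
}
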