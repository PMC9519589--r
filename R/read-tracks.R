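#' Read a track table (and optional CTC-style lineage file) into lineage trees
#'
#' The track file is a UTF-8 tab-separated table with one row per cell per
#' frame and header columns `frame`, `time_h`, `cell_id`, `parent_id` (empty
#' for roots), `x_um`, `y_um`, `end_event` (only on a cell's last row) and
#' `markers` (semicolon-joined subset of `CD41;CD71bright;CD235a`, last row
#' only). This is the corrected output level of automated trackers such as the
#' Baxter algorithm; segmentation/tracking itself is out of scope.
#'
#' If a CTC-style lineage text file (`label begin_frame end_frame parent`,
#' parent 0 = none) is supplied it is taken as the authoritative source of
#' parent links and frame spans, and checked against the track table.
#'
#' @param track_file path to the track TSV.
#' @param lineage_file optional path to a CTC-style lineage text file.
#' @param root_type,condition metadata attached to every reconstructed tree.
#' @param scale pixel-to-micrometre factor applied to `x_um`, `y_um`
#'   (default 1: coordinates already in micrometres).
#' @return a list of [lineage_tree()] objects, one per root.
#' @details End events are inferred in this order: `divided` if the cell has
#'   children; otherwise the endpoint annotation in `end_event`; otherwise
#'   `movie_end` if the track reaches the final frame of the file, else
#'   `lost`.
#' @export
read_tracks <- function(track_file, lineage_file = NULL,
                        root_type = "MEP", condition = "control",
                        scale = 1.0) {
  d <- utils::read.delim(track_file, sep = "\t", header = TRUE,
                         colClasses = c(cell_id = "character",
                                        parent_id = "character",
                                        end_event = "character",
                                        markers = "character"),
                         stringsAsFactors = FALSE)
  need <- c("frame", "time_h", "cell_id", "parent_id", "x_um", "y_um",
            "end_event", "markers")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("track file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop("empty track file: ", track_file)
  d$parent_id[is.na(d$parent_id)] <- ""
  d$end_event[is.na(d$end_event)] <- ""
  d$markers[is.na(d$markers)] <- ""
  d <- d[order(d$cell_id, d$frame), , drop = FALSE]
  if (anyDuplicated(d[c("cell_id", "frame")]))
    stop("duplicate (cell_id, frame) rows in ", track_file)

  lin <- if (!is.null(lineage_file)) read_ctc_lineage(lineage_file)

  last_frame <- max(d$frame)
  rows <- split(seq_len(nrow(d)), d$cell_id)
  ids <- names(rows)

  parent_of <- vapply(rows, function(i) d$parent_id[i[length(i)]], character(1))
  if (!is.null(lin)) {
    if (!setequal(lin$label, ids))
      stop("lineage file cell set differs from track file")
    parent_of <- stats::setNames(
      ifelse(lin$parent == "0", "", lin$parent), lin$label)[ids]
  }
  unresolved <- setdiff(setdiff(unique(parent_of), ""), ids)
  if (length(unresolved))
    stop("unresolvable parent_id(s): ", paste(unresolved, collapse = ", "))

  children_of <- split(ids, factor(parent_of, levels = c("", ids)))
  too_many <- names(children_of)[lengths(children_of) > 2L]
  too_many <- setdiff(too_many, "")
  if (length(too_many))
    stop("cell(s) with more than 2 children: ",
         paste(too_many, collapse = ", "))

  cells <- vector("list", length(ids)); names(cells) <- ids
  for (id in ids) {
    i <- rows[[id]]
    traj <- data.frame(frame = d$frame[i], time = d$time_h[i],
                       x = d$x_um[i] * scale, y = d$y_um[i] * scale)
    kids <- children_of[[id]]
    if (is.null(kids)) kids <- character()
    annot <- d$end_event[i[length(i)]]
    ev <- if (length(kids) == 2L) "divided"
          else if (length(kids) == 1L)
            stop("cell ", id, " has exactly 1 child; divisions are binary")
          else if (nzchar(annot)) annot
          else if (d$frame[i[length(i)]] == last_frame) "movie_end"
          else "lost"
    mk <- d$markers[i[length(i)]]
    markers <- if (nzchar(mk)) strsplit(mk, ";", fixed = TRUE)[[1]] else character()
    pid <- parent_of[[id]]
    cells[[id]] <- cell_record(
      cell_id = id,
      parent_id = if (nzchar(pid)) pid else NA_character_,
      birth_time = d$time_h[i[1L]], end_time = d$time_h[i[length(i)]],
      end_event = ev, markers = markers, trajectory = traj, children = kids)
  }

  root_ids <- ids[parent_of == ""]
  lapply(root_ids, function(r) {
    keep <- r
    queue <- r
    while (length(queue)) {
      id <- queue[1L]; queue <- queue[-1L]
      kids <- cells[[id]]$children
      keep <- c(keep, kids); queue <- c(queue, kids)
    }
    lineage_tree(cells[keep], root_type = root_type, condition = condition)
  })
}

#' Write lineage trees to a track TSV
#'
#' Inverse of [read_tracks()]: emits one row per cell per frame in the track
#' dialect documented there. Cell ids must be unique across the supplied
#' trees.
#'
#' @param trees a `lineage_tree` or list of them.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tracks <- function(trees, file) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  blocks <- lapply(trees, function(tree) {
    do.call(rbind, lapply(tree$cells, function(c) {
      tr <- c$trajectory
      n <- nrow(tr)
      data.frame(
        frame = tr$frame, time_h = tr$time,
        cell_id = c$cell_id,
        parent_id = if (is.na(c$parent_id)) "" else c$parent_id,
        x_um = tr$x, y_um = tr$y,
        end_event = c(rep("", n - 1L),
                      if (c$end_event == "divided") "" else c$end_event),
        markers = c(rep("", n - 1L), paste(c$markers, collapse = ";")),
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, blocks)
  if (is.null(out))
    out <- data.frame(frame = integer(), time_h = numeric(),
                      cell_id = character(), parent_id = character(),
                      x_um = numeric(), y_um = numeric(),
                      end_event = character(), markers = character())
  out <- out[order(out$cell_id, out$frame), , drop = FALSE]
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' Read / write CTC-style lineage text files
#'
#' Whitespace-separated rows `label begin_frame end_frame parent_label`,
#' parent `0` meaning none, as used by cell-tracking benchmark formats.
#'
#' @param file path.
#' @return `read_ctc_lineage`: data frame with columns `label`, `begin`,
#'   `end`, `parent` (all character/integer).
#' @export
read_ctc_lineage <- function(file) {
  d <- utils::read.table(file, header = FALSE,
                         col.names = c("label", "begin", "end", "parent"),
                         colClasses = c("character", "integer", "integer",
                                        "character"))
  d
}

#' @rdname read_ctc_lineage
#' @param trees a `lineage_tree` or list of them.
#' @export
write_ctc_lineage <- function(trees, file) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  rows <- do.call(rbind, lapply(trees, function(tree) {
    do.call(rbind, lapply(tree$cells, function(c) {
      data.frame(label = c$cell_id,
                 begin = c$trajectory$frame[1L],
                 end = c$trajectory$frame[nrow(c$trajectory)],
                 parent = if (is.na(c$parent_id)) "0" else c$parent_id,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows))
    rows <- data.frame(label = character(), begin = integer(),
                       end = integer(), parent = character())
  rows <- rows[order(rows$label), , drop = FALSE]
  utils::write.table(rows, file, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
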