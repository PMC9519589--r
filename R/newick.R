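#' Export a lineage tree to Newick text
#'
#' Branch lengths are cell lifespans in hours; node names are cell ids; when
#' labels are supplied each node carries a bracketed comment of the form
#' `[&fate=<label>]`. The output parses with standard Newick readers
#' (comments are ignorable per the format) and round-trips through
#' [parse_newick()] preserving topology, branch lengths and labels.
#'
#' @param tree a [lineage_tree()].
#' @param labels optional labels from [assign_fate_labels()].
#' @return a single Newick string, `;`-terminated.
#' @export
export_newick <- function(tree, labels = NULL) {
  fmt <- function(id) {
    c <- tree$cells[[id]]
    kids <- c$children
    inner <- if (length(kids))
      paste0("(", paste(vapply(kids, fmt, character(1)), collapse = ","), ")")
    else ""
    comment <- if (!is.null(labels))
      paste0("[&fate=", labels[[id]], "]") else ""
    paste0(inner, id, comment, ":",
           format(c$end_time - c$birth_time, digits = 12, scientific = FALSE,
                  trim = TRUE))
  }
  paste0(fmt(tree$root_id), ";")
}

#' Parse Newick text produced by [export_newick()]
#'
#' A small recursive-descent reader for rooted binary Newick with branch
#' lengths, node names and optional `[&fate=...]` comments. Intended for
#' round-trip checks and light interchange; for general phylogenetics use a
#' dedicated reader.
#'
#' @param text a Newick string.
#' @return data frame with columns `id`, `parent` (`NA` for the root),
#'   `length`, `label` (`NA` when no comment present).
#' @export
parse_newick <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  if (!endsWith(s, ";")) stop("newick text must end with ';'")
  s <- substr(s, 1L, nchar(s) - 1L)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  out <- list()

  read_node <- function(parent) {
    kids <- character()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        read_node(NA_character_) -> kid_id  # parent patched below
        kids <- c(kids, kid_id)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed newick near position ", pos)
      }
    }
    m <- regmatches(substr(s, pos, n),
                    regexpr("^[^][(),:;]*", substr(s, pos, n)))
    id <- m
    pos <<- pos + nchar(m)
    label <- NA_character_
    if (peek() == "[") {
      close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
      if (close < 0) stop("unterminated comment in newick")
      com <- substr(s, pos, pos + close - 1L)
      pos <<- pos + close
      lm <- regmatches(com, regexpr("(?<=&fate=)[^]]*", com, perl = TRUE))
      if (length(lm)) label <- lm
    }
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      lm <- regmatches(substr(s, pos, n),
                       regexpr("^[0-9eE.+-]+", substr(s, pos, n)))
      len <- as.numeric(lm)
      pos <<- pos + nchar(lm)
    }
    if (!nzchar(id)) stop("unnamed newick node not supported")
    out[[length(out) + 1L]] <<- data.frame(
      id = id, parent = parent, length = len, label = label,
      stringsAsFactors = FALSE)
    for (k in kids)
      out[[which(vapply(out, function(r) r$id, character(1)) == k)]]$parent <<- id
    id
  }
  read_node(NA_character_)
  if (pos <= n) stop("trailing characters in newick text")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
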