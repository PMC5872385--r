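#' Construct a signed interaction graph
#'
#' A signed graph is a directed graph whose edges carry an activation
#' (\code{+1}) or inhibition (\code{-1}) sign and a strictly positive weight.
#' It is the qualitative influence-graph representation of a regulatory
#' network: nodes are molecular species (or reaction events) and an edge
#' \code{u -> v} states that \code{u} activates or inhibits \code{v}.
#'
#' Edges are canonicalized on construction: parallel edges with the same
#' source, target and sign are merged by summing their weights, so at most one
#' edge per \code{(source, target, sign)} triple remains.  A pair of
#' opposite-signed edges between the same two nodes is kept as two edges.
#'
#' @param edges a data frame with columns \code{source}, \code{target},
#'   \code{sign} (\code{+1}/\code{-1}) and \code{weight} (positive); the
#'   weight column may be omitted, in which case every edge gets weight 1.
#' @param nodes optional character vector of node identifiers; nodes appearing
#'   in \code{edges} are always included, so this is only needed to declare
#'   isolated nodes.
#' @return an object of class \code{signed_graph}: a list with elements
#'   \code{nodes} (character) and \code{edges} (data frame with columns
#'   \code{source}, \code{target}, \code{sign}, \code{weight}).
#' @seealso [read_signed_graph()], [toy_graph()], [target_nodes()]
#' @export
signed_graph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), weight = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("source", "target", "sign") %in% names(edges)))
      stop("`edges` needs columns source, target, sign", call. = FALSE)
    if (is.null(edges$weight)) edges$weight <- 1
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.integer(edges$sign)
    edges$weight <- as.numeric(edges$weight)
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge signs must be +1 or -1", call. = FALSE)
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("edge weights must be strictly positive", call. = FALSE)
    edges <- canonicalize_edges(edges)
  }
  nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges), class = "signed_graph")
}

# merge parallel same-sign edges by summing weights; stable deterministic order
canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
  w <- tapply(edges$weight, key, sum)
  first <- !duplicated(key)
  out <- edges[first, c("source", "target", "sign"), drop = FALSE]
  out$weight <- as.numeric(w[paste(out$source, out$target, out$sign,
                                   sep = "\r")])
  out <- out[order(out$source, out$target, out$sign), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.signed_graph <- function(x, ...) {
  cat(sprintf("signed graph: %d nodes, %d edges (%d activation, %d inhibition)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' Target nodes of a signed graph
#'
#' A target is a node with at least one predecessor (in-degree >= 1).  Only
#' targets are constrained by the coloring logic; predecessor-free nodes are
#' free variables.
#'
#' @param graph a [signed_graph()].
#' @return character vector of target node ids (sorted).
#' @export
target_nodes <- function(graph) {
  stopifnot(inherits(graph, "signed_graph"))
  sort(unique(graph$edges$target))
}

#' Validate a signed graph prior to coloring
#'
#' The parser accepts self-loops, but the coloring logic does not define
#' self-regulation semantics, so graphs are validated before any coloring or
#' reduction step and self-loops are rejected loudly.
#'
#' @param graph a [signed_graph()].
#' @return the graph, invisibly, if valid.
#' @export
validate_signed_graph <- function(graph) {
  stopifnot(inherits(graph, "signed_graph"))
  loops <- graph$edges$source == graph$edges$target
  if (any(loops))
    stop("graph contains self-loops (",
         paste(unique(graph$edges$source[loops]), collapse = ", "),
         "); self-regulation semantics are undefined", call. = FALSE)
  if (any(graph$edges$weight <= 0))
    stop("graph contains non-positive edge weights", call. = FALSE)
  invisible(graph)
}

.SIGN_TOKENS <- c("1" = 1L, "+1" = 1L, "+" = 1L, "activation" = 1L,
                  "activates" = 1L, "-1" = -1L, "-" = -1L,
                  "inhibition" = -1L, "inhibits" = -1L)

#' Read a signed graph from a tab-separated edge list
#'
#' Accepts the three-column dialect \code{source<TAB>sign<TAB>target} (a
#' SIF-compatible layout where the middle relation token may also be
#' \code{activates}/\code{inhibits}) and the four-column dialect with a
#' trailing \code{weight} column.  Lines starting with \code{#} and blank
#' lines are ignored.  When the weight column is absent every edge gets
#' weight 1.  Duplicate \code{(source, target, sign)} rows are merged by
#' summing weights.
#'
#' @param path path to the edge-list file.
#' @param dialect \code{"auto"} (default, inferred per file), \code{"three-column"}
#'   or \code{"four-column"}.
#' @return a [signed_graph()].
#' @export
read_signed_graph <- function(path, dialect = c("auto", "three-column",
                                                "four-column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(signed_graph())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  want <- switch(dialect, "three-column" = 3L, "four-column" = 4L, NA_integer_)
  bad <- if (is.na(want)) !(n_fields %in% c(3L, 4L)) else n_fields != want
  if (any(bad))
    stop("malformed row at line ", idx[which(bad)[1L]], ": expected ",
         if (is.na(want)) "3 or 4" else want, " tab-separated fields",
         call. = FALSE)
  src <- vapply(parts, `[[`, "", 1L)
  sgn_tok <- trimws(vapply(parts, `[[`, "", 2L))
  tgt <- vapply(parts, `[[`, "", 3L)
  unknown <- !(sgn_tok %in% names(.SIGN_TOKENS))
  if (any(unknown))
    stop("unrecognized sign token '", sgn_tok[which(unknown)[1L]],
         "' at line ", idx[which(unknown)[1L]], call. = FALSE)
  sgn <- unname(.SIGN_TOKENS[sgn_tok])
  w <- rep(1, length(src))
  has_w <- n_fields == 4L
  if (any(has_w)) {
    wtok <- vapply(parts[has_w], `[[`, "", 4L)
    wnum <- suppressWarnings(as.numeric(wtok))
    if (any(is.na(wnum)))
      stop("malformed weight at line ", idx[has_w][which(is.na(wnum))[1L]],
           call. = FALSE)
    if (any(wnum <= 0))
      stop("non-positive weight at line ", idx[has_w][which(wnum <= 0)[1L]],
           call. = FALSE)
    w[has_w] <- wnum
  }
  signed_graph(data.frame(source = src, target = tgt, sign = sgn, weight = w,
                          stringsAsFactors = FALSE))
}

#' Write a signed graph as a four-column TSV edge list
#'
#' The output round-trips losslessly through [read_signed_graph()].  Isolated
#' nodes (no incident edges) are recorded as comment lines so the node set is
#' preserved.
#'
#' @param graph a [signed_graph()].
#' @param path output file path.
#' @export
write_signed_graph <- function(graph, path) {
  stopifnot(inherits(graph, "signed_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# source\tsign\ttarget\tweight", con)
  iso <- setdiff(graph$nodes, c(graph$edges$source, graph$edges$target))
  if (length(iso))
    writeLines(paste0("# node\t", iso), con)
  if (nrow(graph$edges))
    writeLines(sprintf("%s\t%d\t%s\t%s", graph$edges$source, graph$edges$sign,
                       graph$edges$target,
                       format(graph$edges$weight, scientific = FALSE,
                              trim = TRUE)), con)
  invisible(NULL)
}

# read back isolated-node comments written by write_signed_graph
read_signed_graph_full <- function(path) {
  g <- read_signed_graph(path)
  lines <- readLines(path, warn = FALSE)
  iso <- sub("^# node\t", "", grep("^# node\t", lines, value = TRUE))
  signed_graph(g$edges, nodes = c(g$nodes, iso))
}

#' Read an expression matrix and a sample-group table
#'
#' The expression matrix is a TSV whose first column holds gene ids and whose
#' remaining columns hold per-sample values.  The group file is a two-column
#' TSV mapping sample id to \code{case} or \code{control}.
#'
#' @param path path to the expression TSV.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_expression_matrix
#' @param group_path path to the sample-group TSV (columns: sample, group).
#' @return for \code{read_sample_groups}, a named character vector
#'   sample -> group.
#' @export
read_sample_groups <- function(group_path) {
  df <- utils::read.delim(group_path, header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
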