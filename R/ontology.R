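#' Minimal depth of a term in an ontology DAG
#'
#' Length of the shortest root-to-term path in a directed acyclic term
#' ontology given as a child/parent relation (e.g. the is_a edges of the Gene
#' Ontology).  Computed for all terms at once with a breadth-first search
#' from the root.
#'
#' @param dag data frame with columns \code{child}, \code{parent}.
#' @param root root term id.
#' @param term term id (or vector of ids).
#' @return integer vector of minimal depths; errors if a term is unreachable
#'   from the root.
#' @export
min_depth <- function(dag, root, term) {
  d <- term_depths(dag, root)
  missing <- setdiff(term, names(d))
  if (length(missing))
    stop("term(s) unreachable from root: ", paste(missing, collapse = ", "),
         call. = FALSE)
  unname(d[term])
}

#' @rdname min_depth
#' @return for \code{term_depths}, a named integer vector of minimal depths
#'   for every term reachable from the root.
#' @export
term_depths <- function(dag, root) {
  dag <- as.data.frame(dag, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent") %in% names(dag)))
  kids <- split(as.character(dag$child), as.character(dag$parent))
  depth <- stats::setNames(0L, root)
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(kids[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(depth))
    if (length(nxt)) depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

#' Specific-enrichment index of a cluster
#'
#' Fraction of a cluster's enriched ontology terms whose minimal depth is
#' strictly greater than \code{depth_threshold}; deep terms are the specific
#' ones.  The default threshold 7.07 is the mean minimal depth over all
#' biological-process terms of the ontology snapshot used when the metric was
#' calibrated; recompute it from your own snapshot with
#' \code{mean(term_depths(dag, root))} rather than relying on the default.
#'
#' @param term_depth_values numeric vector, minimal depth of each enriched
#'   term of the cluster (enriched means p-value <= 0.05 upstream).
#' @param depth_threshold specificity cut-off (strict inequality).
#' @return fraction in [0, 1]; \code{NA} when the cluster has no enriched
#'   terms.
#' @export
se_index <- function(term_depth_values, depth_threshold = 7.07) {
  if (!length(term_depth_values)) return(NA_real_)
  mean(term_depth_values > depth_threshold)
}

#' Clustering-quality score over enriched clusters
#'
#' \code{CQ = sum_i SE_i * N_i} over clusters, where \code{SE_i} is the
#' specific-enrichment index and \code{N_i} the number of genes of cluster i;
#' clusters with no enriched terms contribute 0.  The companion
#' loss-information ratio relative to a reference clustering is
#' \code{1 - CQ / CQ_ref}.
#'
#' @param clusters list of lists with elements \code{term_depths} (numeric,
#'   possibly empty) and \code{n_genes}.
#' @param depth_threshold see [se_index()].
#' @return the CQ score (numeric scalar).
#' @export
clustering_quality <- function(clusters, depth_threshold = 7.07) {
  if (!length(clusters)) return(0)
  sum(vapply(clusters, function(cl) {
    se <- se_index(cl$term_depths, depth_threshold)
    if (is.na(se)) 0 else se * cl$n_genes
  }, 0))
}

#' @rdname clustering_quality
#' @param cq,cq_ref CQ of the assessed and of the reference clustering.
#' @export
loss_information_ratio <- function(cq, cq_ref) 1 - cq / cq_ref

#' Read a child/parent term DAG from a two-column TSV
#'
#' @param path TSV with columns child, parent (header optional when the first
#'   row parses as data).
#' @return data frame with columns \code{child}, \code{parent}.
#' @export
read_term_dag <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("child", "parent")
  df
}
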