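#' Pairwise coloring-correlation classification
#'
#' For every unordered pair of nodes in a model set, counts in how many
#' optimal colorings the two nodes carry the same sign (\code{a}) and in how
#' many they carry opposite signs (\code{b}).  A pair is positively
#' correlated when \code{b = 0}, negatively correlated when \code{a = 0} and
#' independent when both counts are non-zero.  The diagonal (self-pairs) is
#' excluded.
#'
#' @param models a \code{model_set} from [enumerate_optimal()].
#' @return data frame with columns \code{node1}, \code{node2}, \code{a},
#'   \code{b}, \code{class} (\code{positive}/\code{negative}/\code{independent}).
#' @export
correlation_matrix <- function(models) {
  stopifnot(inherits(models, "model_set"))
  m <- models$colorings
  if (nrow(m) == 0L) stop("empty model set", call. = FALSE)
  nodes <- colnames(m)
  n <- length(nodes)
  if (n < 2L)
    return(data.frame(node1 = character(), node2 = character(),
                      a = integer(), b = integer(), class = character(),
                      stringsAsFactors = FALSE))
  pairs <- utils::combn(n, 2L)
  a <- integer(ncol(pairs)); b <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    same <- m[, pairs[1L, k]] == m[, pairs[2L, k]]
    a[k] <- sum(same)
    b[k] <- sum(!same)
  }
  cls <- ifelse(b == 0L, "positive", ifelse(a == 0L, "negative",
                                            "independent"))
  data.frame(node1 = nodes[pairs[1L, ]], node2 = nodes[pairs[2L, ]],
             a = a, b = b, class = cls, stringsAsFactors = FALSE)
}

#' Identify color-correlated components
#'
#' Positively or negatively correlated node pairs are merged transitively
#' into components; nodes whose colors vary independently across the optimal
#' models (including free, predecessor-less nodes) end up in singleton
#' components, and each edge-balance-isolated subcomponent forms its own
#' component.  When a \code{reduced_graph} is supplied, components over
#' subcomponent representatives are expanded to the original node ids through
#' the stored relative signs.
#'
#' Every component admits exactly two mutually-reversed sign configurations;
#' \code{config1} is canonically the one assigning \code{"up"} to the
#' lexicographically smallest member.
#'
#' @param models a \code{model_set} over the (reduced) graph.
#' @param rg optional \code{reduced_graph} providing isolated subcomponents
#'   and member expansion.
#' @return an object of class \code{component_set}: a list of components,
#'   each a list with \code{id}, \code{members} (named relative-sign vector,
#'   +1 for the smallest member), \code{config1} and \code{config2} (named
#'   \code{up}/\code{down} vectors).
#' @export
identify_components <- function(models, rg = NULL) {
  stopifnot(inherits(models, "model_set"))
  m <- models$colorings
  if (nrow(m) == 0L) stop("empty model set", call. = FALSE)
  nodes <- colnames(m)
  # union-find with relative sign to the root
  parent <- stats::setNames(seq_along(nodes), nodes)
  relsign <- stats::setNames(rep(1, length(nodes)), nodes)
  find <- function(i) {
    s <- 1
    while (parent[i] != i) { s <- s * relsign[i]; i <- parent[i] }
    list(root = i, sign = s)
  }
  if (length(nodes) >= 2L) {
    pairs <- utils::combn(length(nodes), 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      same <- m[, i] == m[, j]
      cls <- if (all(same)) 1 else if (all(!same)) -1 else 0
      if (cls == 0) next
      fi <- find(i); fj <- find(j)
      if (fi$root == fj$root) {
        # coherence: relation along both paths must agree
        stopifnot(fi$sign * fj$sign == cls)
      } else {
        parent[fj$root] <- fi$root
        relsign[fj$root] <- fi$sign * cls * fj$sign
      }
    }
  }
  roots <- vapply(seq_along(nodes), function(i) find(i)$root, 0L)
  signs <- vapply(seq_along(nodes), function(i) find(i)$sign, 0)
  comps <- list()
  for (r in unique(roots)) {
    idx <- which(roots == r)
    mem <- stats::setNames(signs[idx], nodes[idx])
    comps[[length(comps) + 1L]] <- mem
  }
  # expand representatives to original members
  if (!is.null(rg)) {
    stopifnot(inherits(rg, "reduced_graph"))
    subs <- c(rg$subcomponents, rg$isolated)
    comps <- lapply(comps, function(mem) {
      out <- numeric(0)
      for (id in names(mem)) {
        rel <- subs[[id]]
        if (is.null(rel)) rel <- stats::setNames(1, id)
        out <- c(out, mem[[id]] * rel)
      }
      out
    })
    for (id in names(rg$isolated)) {
      covered <- any(vapply(comps, function(mm)
        any(names(rg$isolated[[id]]) %in% names(mm)), TRUE))
      if (!covered)
        comps[[length(comps) + 1L]] <- rg$isolated[[id]]
    }
  }
  comps <- lapply(comps, function(mem) {
    mem <- mem[order(names(mem))]
    mem * mem[[1L]]  # normalize: smallest member positive
  })
  comps <- comps[order(vapply(comps, function(mm) names(mm)[1L], ""))]
  out <- lapply(seq_along(comps), function(i) {
    mem <- comps[[i]]
    config1 <- stats::setNames(ifelse(mem > 0, "up", "down"), names(mem))
    list(id = paste0("C", i), members = mem, config1 = config1,
         config2 = stats::setNames(.flip_sign(config1), names(mem)))
  })
  structure(out, class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component set: %d component(s)\n", length(x)))
  for (comp in x) {
    m <- comp$members
    cat(" ", comp$id, " (", length(m), " nodes): ",
        paste(sprintf("%s%s", names(m), ifelse(m > 0, "+", "-")),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize components as TSV
#'
#' One row per (component, member) with the member's relative sign.
#' @param components a \code{component_set}.
#' @param path output path.
#' @export
write_components <- function(components, path) {
  df <- do.call(rbind, lapply(components, function(comp)
    data.frame(component = comp$id, member = names(comp$members),
               relative_sign = unname(comp$members),
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
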