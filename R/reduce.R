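#' @name graph-reduction
#' @title Behavior-preserving reductions of the coloring solution space
#'
#' @description
#' Three topological reductions shrink a signed graph before coloring while
#' preserving the optimal objective and (after expansion) the optimal model
#' set:
#' \enumerate{
#'   \item \strong{consistency}: a node with a single predecessor and a single
#'     incoming edge is color-correlated with that predecessor in consistent
#'     solutions; the pair is merged into one subcomponent-node, with relative
#'     sign given by the edge sign.
#'   \item \strong{co-regulators}: two predecessor-free nodes sharing the same
#'     unique successor must, in any minimally-imperfect coloring, both
#'     explain that successor; they are merged with relative sign equal to the
#'     product of their edge signs.
#'   \item \strong{edge balance}: between two subcomponents, same-sign edge
#'     weights are summed; an opposite-sign pair (w1, w2) is replaced by the
#'     residual (w1 - min, w2 - min), zero-weight edges are deleted, and the
#'     target is flagged always-consistent / always-imperfect with residual
#'     weight min(w1, w2).  Subcomponents left with no incident edges become
#'     isolated, color-independent components.
#' }
#' Merges are validity-guarded so that the reductions are exact: a
#' consistency merge across an edge lying on any sign-negative cycle is
#' refused, because the cycle forces an inconsistency that optimal colorings
#' may place on that very edge, so the pair carries no universal sign
#' correlation.  Positive cycles collapse cleanly; a subcomponent that
#' absorbed a positive cycle is marked \emph{always consistent} (its entry
#' member stays explained internally in every coloring) and is never itself
#' absorbed upstream, since decoupling it costs imperfection only and can tie
#' with other optima.  Balance-flagged targets are likewise never absorbed.
#' With these guards, enumerating the reduced graph and expanding through the
#' relative signs reproduces the full graph's optimal model set and objective
#' exactly.
NULL

# internal reduction state: members (named list id -> named sign vec, the id
# member anchored at +1), edges (canonical data frame between ids), flags,
# selfcons (ids of subcomponents holding a collapsed positive cycle, which
# keeps them explained internally in every coloring)
.new_state <- function(graph) {
  members <- lapply(graph$nodes, function(v) stats::setNames(1, v))
  names(members) <- graph$nodes
  list(members = members, edges = graph$edges,
       flags = data.frame(node = character(), residual_weight = numeric(),
                          stringsAsFactors = FALSE),
       selfcons = character(0))
}

# merge subcomponent b into a; color(b) = rel * color(a).
# refuses (returns NULL) if any edge between a and b would become a negative
# self-loop; drops positive self-loops (always satisfied internally).
.merge_sub <- function(state, a, b, rel) {
  e <- state$edges
  between <- (e$source == a & e$target == b) | (e$source == b & e$target == a)
  if (any(e$sign[between] * rel == -1)) return(NULL)
  state$members[[a]] <- c(state$members[[a]], rel * state$members[[b]])
  state$members[[b]] <- NULL
  hit_s <- e$source == b
  hit_t <- e$target == b
  e$source[hit_s] <- a
  e$target[hit_t] <- a
  e$sign[hit_s] <- e$sign[hit_s] * rel
  e$sign[hit_t] <- e$sign[hit_t] * rel
  loops <- e$source == e$target
  stopifnot(all(e$sign[loops] == 1L))
  # a back-edge b -> a closing a positive cycle keeps the merged
  # subcomponent's entry member explained internally in every coloring; the
  # consumed pattern edge a -> b explains only the absorbed member, whose
  # other in-edges are none, and marks nothing
  closes_cycle <- any(loops & hit_s & !hit_t)
  if (closes_cycle || b %in% state$selfcons)
    state$selfcons <- union(state$selfcons, a)
  state$selfcons <- setdiff(state$selfcons, b)
  e <- e[!loops, , drop = FALSE]
  state$edges <- canonicalize_edges(e)
  if (nrow(state$flags) && b %in% state$flags$node) {
    state$flags$node[state$flags$node == b] <- a
    state$flags <- .normalize_flags(state$flags)
  }
  state
}

# TRUE when the edge s -> v (sign `sign0`) lies on some negative cycle,
# i.e. a path v ~> s of sign -sign0 exists.  Sign-parity BFS over
# (node, parity) pairs; conservative (any such cycle suffices to refuse).
.on_negative_cycle <- function(edges, v, s, sign0) {
  need <- -sign0
  reached <- paste(v, 1L)
  frontier <- reached
  while (length(frontier)) {
    parts <- strsplit(frontier, " ", fixed = TRUE)
    nxt <- character(0)
    for (p in parts) {
      node <- p[1L]; par <- as.integer(p[2L])
      out <- which(edges$source == node)
      key <- paste(edges$target[out], par * edges$sign[out])
      nxt <- c(nxt, key[!(key %in% reached)])
    }
    nxt <- unique(nxt)
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  paste(s, need) %in% reached
}

.reduce_consistency_state <- function(state) {
  repeat {
    e <- state$edges
    if (nrow(e) == 0L) return(state)
    merged <- FALSE
    in_deg <- table(factor(e$target, levels = unique(e$target)))
    for (v in sort(names(in_deg)[in_deg == 1L])) {
      row <- which(state$edges$target == v)
      if (length(row) != 1L) next  # state changed earlier in the loop
      s <- state$edges$source[row]
      if (s == v) next
      # a self-consistent or balance-flagged node can decouple from its
      # remaining predecessor at imperfection cost only, so its color is not
      # forced by that edge in every optimum: never absorb it upstream
      if (v %in% state$selfcons || v %in% state$flags$node) next
      # an edge on a negative cycle carries no universal sign correlation:
      # the cycle forces an inconsistency that optimal colorings may place
      # on this very edge, so merging across it would discard tied optima
      if (.on_negative_cycle(state$edges, v, s, state$edges$sign[row]))
        next
      st2 <- .merge_sub(state, s, v, state$edges$sign[row])
      if (is.null(st2)) next  # would close a negative cycle
      state <- st2
      merged <- TRUE
    }
    if (!merged) return(state)
  }
}

.reduce_coregulators_state <- function(state, strict = FALSE) {
  repeat {
    e <- state$edges
    if (nrow(e) == 0L) return(state)
    has_pred <- unique(e$target)
    out_rows <- split(seq_len(nrow(e)), e$source)
    cand <- names(out_rows)[!(names(out_rows) %in% has_pred) &
                              lengths(out_rows) == 1L]
    if (!length(cand)) return(state)
    rows <- vapply(out_rows[cand], `[[`, 0L, 1L)
    info <- data.frame(id = cand, succ = e$target[rows], sign = e$sign[rows],
                       stringsAsFactors = FALSE)
    merged <- FALSE
    for (z in unique(info$succ)) {
      grp <- info[info$succ == z, , drop = FALSE]
      if (nrow(grp) < 2L) next
      grp <- grp[order(grp$id), , drop = FALSE]
      x <- grp$id[1L]; y <- grp$id[2L]
      if (strict && grp$sign[1L] != grp$sign[2L]) {
        same <- grp[grp$sign == grp$sign[1L], , drop = FALSE]
        if (nrow(same) < 2L) next
        x <- same$id[1L]; y <- same$id[2L]
      }
      rel <- grp$sign[grp$id == x] * grp$sign[grp$id == y]
      st2 <- .merge_sub(state, x, y, rel)
      if (is.null(st2)) next
      state <- st2
      merged <- TRUE
      break  # edge table changed; rescan
    }
    if (!merged) return(state)
  }
}

.reduce_edge_balance_state <- function(state) {
  e <- canonicalize_edges(state$edges)
  if (nrow(e) == 0L) { state$edges <- e; return(state) }
  key <- paste(e$source, e$target, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)   # exactly 2 rows, opposite signs
    w1 <- e$weight[idx[1L]]; w2 <- e$weight[idx[2L]]
    m <- min(w1, w2)
    e$weight[idx[1L]] <- w1 - m
    e$weight[idx[2L]] <- w2 - m
    state$flags <- rbind(state$flags,
                         data.frame(node = e$target[idx[1L]],
                                    residual_weight = m,
                                    stringsAsFactors = FALSE))
  }
  state$flags <- .normalize_flags(state$flags)
  state$edges <- e[e$weight > 0, , drop = FALSE]
  state
}

# orient each subcomponent on its lexicographically smallest member and
# rename ids accordingly (representative convention)
.finalize_state <- function(state, graph) {
  reps <- character(0)
  for (id in names(state$members)) {
    mem <- state$members[[id]]
    rep <- min(names(mem))
    if (mem[[rep]] == -1) {
      mem <- -mem
      flip_s <- state$edges$source == id
      flip_t <- state$edges$target == id
      state$edges$sign[flip_s] <- -state$edges$sign[flip_s]
      state$edges$sign[flip_t] <- -state$edges$sign[flip_t]
    }
    state$members[[id]] <- mem[order(names(mem))]
    reps[id] <- rep
  }
  state$edges$source <- unname(reps[state$edges$source])
  state$edges$target <- unname(reps[state$edges$target])
  if (nrow(state$flags))
    state$flags$node <- unname(reps[state$flags$node])
  names(state$members) <- unname(reps[names(state$members)])
  state$edges <- canonicalize_edges(state$edges)
  incident <- unique(c(state$edges$source, state$edges$target))
  iso_ids <- setdiff(names(state$members), incident)
  structure(list(
    graph = signed_graph(state$edges, nodes = incident),
    subcomponents = state$members[setdiff(names(state$members), iso_ids)],
    isolated = state$members[iso_ids],
    flags = state$flags,
    always_consistent = sort(unname(reps[state$selfcons])),
    original = graph), class = "reduced_graph")
}

.state_of <- function(rg) {
  list(members = c(rg$subcomponents, rg$isolated), edges = rg$graph$edges,
       flags = rg$flags, selfcons = rg$always_consistent)
}

#' Wrap a signed graph as an unreduced reduced-graph
#'
#' Every node becomes a singleton subcomponent; no reduction is applied.
#' @param graph a [signed_graph()].
#' @return a \code{reduced_graph}.
#' @export
as_reduced_graph <- function(graph) {
  validate_signed_graph(graph)
  .finalize_state(.new_state(graph), graph)
}

#' @describeIn graph-reduction apply the consistency reduction to fixpoint.
#' @param rg a \code{reduced_graph} (see [as_reduced_graph()], [reduce_all()]).
#' @export
reduce_consistency <- function(rg) {
  stopifnot(inherits(rg, "reduced_graph"))
  .finalize_state(.reduce_consistency_state(.state_of(rg)), rg$original)
}

#' @describeIn graph-reduction apply the co-regulator reduction to fixpoint.
#' @param strict if \code{TRUE}, only merge co-regulator pairs whose edges
#'   carry the same sign (the literal two-activator pattern); the default
#'   also merges mixed-sign pairs with relative sign -1.
#' @export
reduce_coregulators <- function(rg, strict = FALSE) {
  stopifnot(inherits(rg, "reduced_graph"))
  .finalize_state(.reduce_coregulators_state(.state_of(rg), strict),
                  rg$original)
}

#' @describeIn graph-reduction apply the edge-balance reduction once.
#' @export
reduce_edge_balance <- function(rg) {
  stopifnot(inherits(rg, "reduced_graph"))
  .finalize_state(.reduce_edge_balance_state(.state_of(rg)), rg$original)
}

#' Reduce a signed graph with all three reductions
#'
#' Wraps every node as a singleton subcomponent, applies the consistency
#' reduction to fixpoint, then the co-regulator reduction to fixpoint, then
#' the edge-balance reduction -- the successive order of the workflow.  A
#' co-regulator merge can expose a fresh single-predecessor pattern (the
#' merged pair's summed edge); by default the earlier reductions are
#' \emph{not} re-entered, so the reduced graph matches the successive
#' narrative step for step, and component identification picks up the
#' remaining correlations anyway.  Set \code{interleave = TRUE} to iterate
#' reductions 1 and 2 to their joint fixpoint, and
#' \code{rerun_after_balance = TRUE} to also re-enter the merge loop after
#' balance deletions; every variant preserves the optimum.
#'
#' @param graph a [signed_graph()].
#' @param strict_coregulators see [reduce_coregulators()].
#' @param interleave iterate consistency + co-regulator reductions to their
#'   joint fixpoint instead of one pass each.
#' @param rerun_after_balance re-enter the merge fixpoint after edge-balance
#'   deletions expose new patterns.
#' @return an object of class \code{reduced_graph}: list with \code{graph}
#'   (the [signed_graph()] over non-isolated subcomponent representatives),
#'   \code{subcomponents} and \code{isolated} (named lists mapping
#'   representative id to a named member -> relative-sign vector),
#'   \code{flags} (always-consistent/always-imperfect targets with residual
#'   weights) and \code{original}.
#' @export
reduce_all <- function(graph, strict_coregulators = FALSE,
                       interleave = FALSE, rerun_after_balance = FALSE) {
  stopifnot(inherits(graph, "signed_graph"))
  validate_signed_graph(graph)
  state <- .new_state(graph)
  iterations <- 0L
  repeat {
    repeat {
      n_before <- length(state$members)
      state <- .reduce_consistency_state(state)
      state <- .reduce_coregulators_state(state, strict_coregulators)
      iterations <- iterations + 1L
      if (!interleave || length(state$members) == n_before) break
    }
    sig <- paste(nrow(state$edges), length(state$members))
    state <- .reduce_edge_balance_state(state)
    changed <- !identical(sig, paste(nrow(state$edges),
                                     length(state$members)))
    if (!rerun_after_balance || !changed) break
  }
  rg <- .finalize_state(state, graph)
  rg$iterations <- iterations
  rg
}

#' @export
print.reduced_graph <- function(x, ...) {
  cat(sprintf(
    "reduced graph: %d subcomponent node(s), %d edge(s), %d isolated, %d flagged\n",
    length(x$subcomponents), nrow(x$graph$edges), length(x$isolated),
    nrow(x$flags)))
  for (id in names(x$subcomponents)) {
    m <- x$subcomponents[[id]]
    cat(" ", id, ": ",
        paste(sprintf("%s%s", names(m), ifelse(m > 0, "+", "-")),
              collapse = ", "), "\n", sep = "")
  }
  for (id in names(x$isolated)) {
    m <- x$isolated[[id]]
    cat("  [isolated] ", id, ": ",
        paste(sprintf("%s%s", names(m), ifelse(m > 0, "+", "-")),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# objective contribution of flagged targets that became isolated (no edges
# left): always one imperfect target with the residual weight, whatever the
# coloring.  enumerate_optimal only sees flags on connected nodes.
.flag_split <- function(rg) {
  conn <- rg$flags$node %in% rg$graph$nodes
  list(connected = rg$flags[conn, , drop = FALSE],
       offset = c(n_inconsistent = 0,
                  n_imperfect = sum(!conn),
                  imperfect_weight = sum(rg$flags$residual_weight[!conn])))
}

#' Expand a reduced-graph coloring to the original nodes
#'
#' Each member of a colored subcomponent receives the subcomponent's color
#' composed with its relative sign (+1 keeps the color, -1 flips it).
#' Representatives absent from \code{coloring} (e.g. unassigned isolated
#' subcomponents) are simply omitted from the result.
#'
#' @param rg a \code{reduced_graph}.
#' @param coloring named \code{up}/\code{down} vector over representative ids.
#' @return named \code{up}/\code{down} vector over the covered original nodes.
#' @export
expand_coloring <- function(rg, coloring) {
  stopifnot(inherits(rg, "reduced_graph"))
  all_subs <- c(rg$subcomponents, rg$isolated)
  missing <- setdiff(names(coloring), names(all_subs))
  if (length(missing))
    stop("unknown subcomponent id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!names(rg$subcomponents) %in% names(coloring)))
    stop("coloring must cover every non-isolated subcomponent",
         call. = FALSE)
  out <- character(0)
  for (id in names(coloring)) {
    mem <- all_subs[[id]]
    up <- coloring[[id]] == "up"
    vals <- ifelse((mem > 0) == up, "up", "down")
    out <- c(out, stats::setNames(vals, names(mem)))
  }
  out[order(names(out))]
}

#' Expand a reduced model set to original-node colorings
#'
#' Every reduced optimal coloring is expanded through the subcomponent
#' relative signs; optionally the isolated subcomponents, whose colors are
#' unconstrained, are completed with both orientations (cross product), which
#' reconstructs the full-graph optimal model set.
#'
#' @param rg a \code{reduced_graph}.
#' @param models a \code{model_set} over \code{rg$graph}.
#' @param include_isolated complete isolated subcomponents both ways.
#' @return character matrix of colorings over original node ids.
#' @export
expand_models <- function(rg, models, include_isolated = TRUE) {
  stopifnot(inherits(rg, "reduced_graph"), inherits(models, "model_set"))
  iso <- names(rg$isolated)
  k <- if (include_isolated) length(iso) else 0L
  iso_grid <- if (k > 0) {
    g <- as.matrix(expand.grid(rep(list(c("down", "up")), k),
                               KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
    colnames(g) <- iso
    g
  } else matrix(character(), nrow = 1L, ncol = 0L)
  rows <- list()
  for (i in seq_len(nrow(models$colorings))) {
    base <- models$colorings[i, ]
    for (j in seq_len(nrow(iso_grid))) {
      col <- c(base, stats::setNames(iso_grid[j, ], colnames(iso_grid)))
      rows[[length(rows) + 1L]] <- expand_coloring(rg, col)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(apply(out, 1L, paste, collapse = "\r")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a reduced graph
#'
#' Writes three TSVs next to each other: the reduced edge list
#' (\code{<stem>.edges.tsv}), the membership table
#' (\code{<stem>.members.tsv}: member, representative, relative_sign,
#' isolated) and the flags table (\code{<stem>.flags.tsv}).
#'
#' @param rg a \code{reduced_graph}.
#' @param stem output path stem.
#' @export
write_reduced_graph <- function(rg, stem) {
  write_signed_graph(rg$graph, paste0(stem, ".edges.tsv"))
  all_subs <- c(rg$subcomponents, rg$isolated)
  mem <- do.call(rbind, lapply(names(all_subs), function(id)
    data.frame(member = names(all_subs[[id]]), representative = id,
               relative_sign = unname(all_subs[[id]]),
               isolated = id %in% names(rg$isolated),
               stringsAsFactors = FALSE)))
  utils::write.table(mem, paste0(stem, ".members.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rg$flags, paste0(stem, ".flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
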