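#' Does a predecessor explain a target's color?
#'
#' The local sign-consistency rule: along an activation edge the predecessor
#' must carry the same sign as the target; along an inhibition edge it must
#' carry the opposite sign.
#'
#' @param pred_sign,target_sign \code{"up"} or \code{"down"}.
#' @param edge_sign \code{+1} (activation) or \code{-1} (inhibition).
#' @return logical.
#' @export
explains <- function(pred_sign, edge_sign, target_sign) {
  (edge_sign == 1L) == (pred_sign == target_sign)
}

#' Evaluate a coloring against the perfectness logic
#'
#' A coloring assigns \code{"up"} or \code{"down"} to every node.  For each
#' target (node with at least one predecessor) three things are assessed:
#' whether it is \emph{consistent} (explained by at least one incoming edge),
#' whether it is \emph{imperfect} (at least one incoming edge fails to
#' explain it), and the summed weight of its imperfect regulators.  The
#' objective vector is the lexicographic triple
#' (number of inconsistent targets, number of imperfect targets, total
#' imperfect-regulator weight).
#'
#' Flags produced by the edge-balance reduction mark targets that are always
#' consistent yet always imperfect: such a target's flag contributes its
#' stored residual weight to the third objective regardless of the coloring,
#' so a reduced graph reports the same objective as the graph it came from.
#' Nodes listed in \code{always_consistent} (subcomponents holding a
#' collapsed positive cycle, which explains them internally in every
#' coloring) are never counted inconsistent, but their incoming edges are
#' scored normally.
#'
#' @param graph a [signed_graph()].
#' @param coloring named character vector (\code{"up"}/\code{"down"}), one
#'   entry per node of \code{graph}.
#' @param flags optional data frame with columns \code{node},
#'   \code{residual_weight} (from [reduce_all()]).
#' @param always_consistent optional character vector of nodes explained
#'   internally in every coloring (from [reduce_all()]).
#' @return a list with \code{objective} (named numeric triple
#'   \code{n_inconsistent}, \code{n_imperfect}, \code{imperfect_weight}) and
#'   \code{status}, a data frame with one row per target: \code{node},
#'   \code{consistent}, \code{imperfect}, \code{imperfect_weight}, plus a
#'   list-column \code{imperfect_regulators} of data frames
#'   (\code{source}, \code{sign}, \code{weight}).
#' @export
evaluate_coloring <- function(graph, coloring, flags = NULL,
                              always_consistent = character()) {
  stopifnot(inherits(graph, "signed_graph"))
  validate_signed_graph(graph)
  missing <- setdiff(graph$nodes, names(coloring))
  if (length(missing))
    stop("coloring is missing nodes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(coloring %in% c("up", "down")))
    stop("coloring values must be 'up' or 'down'", call. = FALSE)
  flags <- .normalize_flags(flags)
  e <- graph$edges
  targets <- sort(unique(c(e$target, flags$node)))
  expl <- if (nrow(e)) explains(coloring[e$source], e$sign, coloring[e$target])
          else logical()
  status <- data.frame(node = targets, consistent = FALSE, imperfect = FALSE,
                       imperfect_weight = 0, stringsAsFactors = FALSE)
  regs <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    t <- targets[i]
    idx <- which(e$target == t)
    ok <- expl[idx]
    flagged <- t %in% flags$node
    status$consistent[i] <- any(ok) || flagged || t %in% always_consistent
    bad <- idx[!ok]
    res_w <- if (flagged) flags$residual_weight[flags$node == t] else 0
    status$imperfect[i] <- length(bad) > 0L || flagged
    status$imperfect_weight[i] <- sum(e$weight[bad]) + res_w
    regs[[i]] <- data.frame(source = e$source[bad], sign = e$sign[bad],
                            weight = e$weight[bad], stringsAsFactors = FALSE)
  }
  status$imperfect_regulators <- regs
  objective <- c(n_inconsistent = sum(!status$consistent),
                 n_imperfect = sum(status$imperfect),
                 imperfect_weight = sum(status$imperfect_weight))
  list(objective = objective, status = status)
}

.normalize_flags <- function(flags) {
  if (is.null(flags) || nrow(as.data.frame(flags)) == 0L)
    return(data.frame(node = character(), residual_weight = numeric(),
                      stringsAsFactors = FALSE))
  flags <- as.data.frame(flags, stringsAsFactors = FALSE)
  stopifnot(all(c("node", "residual_weight") %in% names(flags)))
  if (anyDuplicated(flags$node)) {
    w <- tapply(flags$residual_weight, flags$node, sum)
    flags <- data.frame(node = names(w), residual_weight = as.numeric(w),
                        stringsAsFactors = FALSE)
  }
  flags
}

# integer-scaled objective triple for one coloring matrix row block.
# colmat: logical matrix (TRUE = up), columns named by node.
# returns matrix with columns inc, imp, w (w integer-scaled).
.objective_matrix <- function(graph, colmat, flags,
                              always_consistent = character()) {
  e <- graph$edges
  n_flag <- nrow(flags)
  res_w <- sum(.scale_weight(flags$residual_weight))
  if (nrow(e) == 0L) {
    return(cbind(inc = 0L, imp = rep(n_flag, nrow(colmat)),
                 w = rep(res_w, nrow(colmat))))
  }
  targets <- sort(unique(c(e$target, flags$node)))
  tix <- match(e$target, targets)
  sw <- .scale_weight(e$weight)
  nr <- nrow(colmat)
  # per-edge explained matrix: rows colorings, cols edges
  same <- colmat[, e$source, drop = FALSE] == colmat[, e$target, drop = FALSE]
  expl <- sweep(same, 2L, e$sign == 1L, `==`)
  cons <- matrix(FALSE, nr, length(targets))
  nimp <- matrix(0L, nr, length(targets))
  wimp <- matrix(0, nr, length(targets))
  for (j in seq_along(e$target)) {
    k <- tix[j]
    cons[, k] <- cons[, k] | expl[, j]
    nimp[, k] <- nimp[, k] + !expl[, j]
    wimp[, k] <- wimp[, k] + sw[j] * !expl[, j]
  }
  flagged <- targets %in% flags$node
  cons[, flagged | targets %in% always_consistent] <- TRUE
  imp <- nimp > 0L
  imp[, flagged] <- TRUE
  cbind(inc = rowSums(!cons),
        imp = rowSums(imp),
        w = rowSums(wimp) + res_w)
}

#' Enumerate all lexicographically optimal colorings
#'
#' Searches the \eqn{2^n} space of total up/down colorings for the complete
#' set minimizing the objective triple (inconsistent targets, imperfect
#' targets, imperfect-regulator weight) in that priority order.  Two exact
#' backends are provided: \code{"bruteforce"} scans the whole space
#' (vectorized, capped at \code{cap} nodes) and \code{"branchbound"} performs
#' depth-first search with a lexicographic lower bound, still collecting
#' \emph{every} optimum.  The \code{"asp"} backend grounds and solves the
#' program emitted by [emit_asp_program()] with an external \code{clingo}
#' solver if one is on the PATH, and fails loudly otherwise.
#'
#' Because the consistency rules are symmetric in the two signs, the optimum
#' set is closed under the global flip of all colors whenever no node is
#' fixed; fixing one node (\code{fixed}) halves the search space and the flip
#' closure can be restored afterwards with [flip_complete()].
#'
#' @param graph a [signed_graph()] (typically the reduced graph).
#' @param fixed optional length-1 named character vector, e.g.
#'   \code{c(A = "down")}, pinning one node's color.
#' @param flags optional always-consistent/always-imperfect target flags
#'   (see [evaluate_coloring()]).
#' @param always_consistent see [evaluate_coloring()].
#' @param backend \code{"branchbound"} (default), \code{"bruteforce"} or
#'   \code{"asp"}.
#' @param cap refusal threshold on node count for the bruteforce backend.
#' @return an object of class \code{model_set}: a list with
#'   \code{colorings} (character matrix, one row per optimal coloring, columns
#'   named by node), \code{objective} (named numeric triple), \code{fixed},
#'   and \code{free} (nodes with no incident edges, whose colors are
#'   unconstrained and double the model count).
#' @export
enumerate_optimal <- function(graph, fixed = NULL, flags = NULL,
                              always_consistent = character(),
                              backend = c("branchbound", "bruteforce", "asp"),
                              cap = 20L) {
  backend <- match.arg(backend)
  stopifnot(inherits(graph, "signed_graph"))
  validate_signed_graph(graph)
  flags <- .normalize_flags(flags)
  if (!all(flags$node %in% graph$nodes))
    stop("flagged nodes absent from graph", call. = FALSE)
  if (!is.null(fixed)) {
    if (length(fixed) != 1L || is.null(names(fixed)) ||
        !names(fixed) %in% graph$nodes || !fixed %in% c("up", "down"))
      stop("`fixed` must be a single named 'up'/'down' entry over graph nodes",
           call. = FALSE)
  }
  nodes <- graph$nodes
  free <- setdiff(nodes, unique(c(graph$edges$source, graph$edges$target)))
  if (length(nodes) == 0L) {
    m <- matrix(character(), nrow = 1L, ncol = 0L)
    return(structure(list(colorings = m,
                          objective = c(n_inconsistent = 0,
                                        n_imperfect = nrow(flags),
                                        imperfect_weight =
                                          sum(flags$residual_weight)),
                          fixed = fixed, free = free),
                     class = "model_set"))
  }
  res <- switch(backend,
    bruteforce = .enumerate_bruteforce(graph, fixed, flags, always_consistent,
                                       cap),
    branchbound = .enumerate_branchbound(graph, fixed, flags,
                                         always_consistent),
    asp = .enumerate_asp(graph, fixed, flags, always_consistent))
  colorings <- res$colorings
  ord <- order(apply(colorings, 1L, paste, collapse = "\r"))
  colorings <- colorings[ord, , drop = FALSE]
  rownames(colorings) <- NULL
  structure(list(colorings = colorings,
                 objective = c(n_inconsistent = res$obj[1L],
                               n_imperfect = res$obj[2L],
                               imperfect_weight = res$obj[3L] /
                                 as.numeric(.WSCALE)),
                 fixed = fixed, free = free),
            class = "model_set")
}

.enumerate_bruteforce <- function(graph, fixed, flags, always_consistent,
                                  cap) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n > cap)
    stop("bruteforce backend refused: ", n, " nodes exceeds cap ", cap,
         call. = FALSE)
  vary <- nodes
  base <- logical(0)
  if (!is.null(fixed)) {
    vary <- setdiff(nodes, names(fixed))
    base <- stats::setNames(fixed == "up", names(fixed))
  }
  k <- length(vary)
  grid <- matrix(FALSE, nrow = 2^k, ncol = n, dimnames = list(NULL, nodes))
  if (k > 0) {
    bits <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k),
                                  KEEP.OUT.ATTRS = FALSE))
    grid[, vary] <- bits
  }
  if (length(base)) grid[, names(base)] <- rep(base, each = nrow(grid))
  obj <- .objective_matrix(graph, grid, flags, always_consistent)
  best <- .lex_min_rows(obj)
  keep <- obj[, 1L] == best[1L] & obj[, 2L] == best[2L] & obj[, 3L] == best[3L]
  colorings <- ifelse(grid[keep, , drop = FALSE], "up", "down")
  list(colorings = colorings, obj = best)
}

.lex_min_rows <- function(obj) {
  m1 <- min(obj[, 1L]); s <- obj[, 1L] == m1
  m2 <- min(obj[s, 2L]); s <- s & obj[, 2L] == m2
  m3 <- min(obj[s, 3L])
  c(m1, m2, m3)
}

# depth-first branch and bound collecting the complete optimum set.
# nodes are ordered so that targets appear after as many of their
# predecessors as possible; a target's contribution is added to the bound as
# soon as it and all its predecessors are assigned.
.enumerate_branchbound <- function(graph, fixed, flags,
                                   always_consistent = character()) {
  nodes <- graph$nodes
  n <- length(nodes)
  e <- graph$edges
  # order: approximate topological-ish order by in-degree-weighted DFS is
  # overkill; simple heuristic: sort by (number of incident edges) descending
  # so constrained nodes are decided early
  deg <- table(factor(c(e$source, e$target), levels = nodes))
  ord <- order(-as.integer(deg), nodes)
  nodes <- nodes[ord]
  pos <- match(c(e$source, e$target), nodes)
  # for each target, the depth at which it becomes fully decided
  targets <- sort(unique(c(e$target, flags$node)))
  decided_at <- vapply(targets, function(t) {
    idx <- which(e$target == t)
    max(match(t, nodes), if (length(idx)) match(e$source[idx], nodes) else 0L)
  }, integer(1))
  # group targets by decision depth
  by_depth <- split(targets, decided_at)
  sw <- .scale_weight(e$weight)
  flag_nodes <- flags$node
  res_by_target <- stats::setNames(rep(0, length(targets)), targets)
  if (nrow(flags))
    res_by_target[flags$node] <- .scale_weight(flags$residual_weight)
  edges_by_target <- split(seq_len(nrow(e)), e$target)

  best <- c(Inf, Inf, Inf)
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()

  assign_vec <- stats::setNames(rep(NA, n), nodes)
  fixed_name <- if (!is.null(fixed)) names(fixed) else NULL

  target_obj <- function(t, a) {
    idx <- edges_by_target[[t]]
    flagged <- t %in% flag_nodes
    if (is.null(idx)) {
      # flagged target with no remaining in-edges
      return(c(0L, 1L, res_by_target[[t]]))
    }
    ok <- (e$sign[idx] == 1L) == (a[e$source[idx]] == a[t])
    cons <- any(ok) || flagged || t %in% always_consistent
    imp <- any(!ok) || flagged
    c(as.integer(!cons), as.integer(imp),
      sum(sw[idx][!ok]) + if (flagged) res_by_target[[t]] else 0)
  }

  recurse <- function(depth, a, bound) {
    if (.lex_cmp(bound, best) > 0L) return()
    if (depth > n) {
      cmp <- .lex_cmp(bound, best)
      if (cmp < 0L) {
        best <<- bound
        acc$rows <- list(a)
      } else if (cmp == 0L) {
        acc$rows[[length(acc$rows) + 1L]] <- a
      }
      return()
    }
    v <- nodes[depth]
    vals <- if (!is.null(fixed_name) && v == fixed_name) fixed[[1L]]
            else c("down", "up")
    newly <- by_depth[[as.character(depth)]]
    for (val in vals) {
      a[v] <- val
      b <- bound
      if (!is.null(newly))
        for (t in newly) b <- b + target_obj(t, a)
      recurse(depth + 1L, a, b)
    }
  }
  base_bound <- c(0, 0, 0)
  # flagged targets with no in-edges never appear in by_depth keyed at a
  # positive depth only if they are graph nodes; handle zero-depth flags
  zero <- by_depth[["0"]]
  if (!is.null(zero))
    for (t in zero) base_bound <- base_bound + c(0L, 1L, res_by_target[[t]])
  recurse(1L, assign_vec, base_bound)
  colorings <- do.call(rbind, acc$rows)
  colorings <- colorings[, graph$nodes, drop = FALSE]
  list(colorings = colorings, obj = best)
}

#' Restore the global-flip closure of a model set
#'
#' When one node was fixed to halve the search space, every optimum's global
#' reverse is also an optimum of the unfixed problem; this adds the missing
#' reversed colorings back.
#'
#' @param models a \code{model_set}.
#' @return a \code{model_set} with \code{fixed = NULL} and the flip-closed
#'   coloring set.
#' @export
flip_complete <- function(models) {
  stopifnot(inherits(models, "model_set"))
  m <- models$colorings
  flipped <- matrix(.flip_sign(m), nrow = nrow(m), dimnames = dimnames(m))
  all <- rbind(m, flipped)
  key <- apply(all, 1L, paste, collapse = "\r")
  all <- all[!duplicated(key), , drop = FALSE]
  all <- all[order(apply(all, 1L, paste, collapse = "\r")), , drop = FALSE]
  rownames(all) <- NULL
  models$colorings <- all
  models$fixed <- NULL
  models
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("model set: %d optimal coloring(s) over %d node(s)\n",
              nrow(x$colorings), ncol(x$colorings)))
  cat(sprintf("objective: %d inconsistent, %d imperfect, weight %s\n",
              x$objective[["n_inconsistent"]], x$objective[["n_imperfect"]],
              format(x$objective[["imperfect_weight"]])))
  if (!is.null(x$fixed))
    cat(sprintf("fixed: %s = %s\n", names(x$fixed), x$fixed))
  if (length(x$free))
    cat("free nodes:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Write a model set as TSV
#'
#' One row per coloring, one column per node, cells \code{up}/\code{down}.
#' @param models a \code{model_set}.
#' @param path output path.
#' @export
write_model_set <- function(models, path) {
  df <- as.data.frame(models$colorings, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Emit the coloring problem as an ASP program
#'
#' Produces an ASP-Core-2 (gringo dialect) encoding of the perfectness
#' optimization: edge facts, derived node/target predicates, a choice rule
#' generating candidate colorings, consistency/imperfection definitions and
#' three \code{#minimize} statements at priorities 3 (inconsistent targets),
#' 2 (imperfect targets) and 1 (imperfect-regulator weight).  Grounding and
#' solving the text with clingo enumerates the same optimum set as
#' [enumerate_optimal()].
#'
#' @param graph a [signed_graph()].
#' @param fixed optional single named \code{up}/\code{down} fixing fact.
#' @param flags optional edge-balance flags; flagged targets are asserted
#'   consistent and imperfect with their residual weight.
#' @param always_consistent nodes asserted consistent (collapsed positive
#'   cycles).
#' @return character scalar, the program text.
#' @export
emit_asp_program <- function(graph, fixed = NULL, flags = NULL,
                             always_consistent = character()) {
  stopifnot(inherits(graph, "signed_graph"))
  flags <- .normalize_flags(flags)
  q <- function(x) paste0("\"", x, "\"")
  e <- graph$edges
  out <- c("% perfect-coloring encoding (ASP-Core-2 / gringo)",
           "sign(up;down).")
  if (nrow(e))
    out <- c(out, sprintf("edge(%s,%s,%d,%d).", q(e$source), q(e$target),
                          e$sign, .scale_weight(e$weight)))
  out <- c(out,
    if (length(graph$nodes)) sprintf("node(%s).", q(graph$nodes)),
    "node(X) :- edge(X,_,_,_).",
    "node(X) :- edge(_,X,_,_).",
    "target(X) :- edge(_,X,_,_).",
    "% candidate colorings: exactly one sign per node",
    "1 { color(X,S) : sign(S) } 1 :- node(X).",
    "% local consistency: some incoming edge explains the target",
    "consistent(N) :- edge(P,N,1,_), color(P,S), color(N,S).",
    "consistent(N) :- edge(P,N,-1,_), color(P,S1), color(N,S2), S1 != S2.",
    "inconsistent(N) :- target(N), not consistent(N).",
    "% imperfect regulators: incoming edges failing to explain",
    "imperfectReg(P,N,W) :- edge(P,N,1,W), color(P,S1), color(N,S2), S1 != S2.",
    "imperfectReg(P,N,W) :- edge(P,N,-1,W), color(P,S), color(N,S).",
    "imperfect(N) :- imperfectReg(_,N,_).")
  if (nrow(flags))
    out <- c(out,
      "% edge-balance flags: always consistent, always imperfect",
      sprintf("consistent(%s).", q(flags$node)),
      sprintf("imperfect(%s).", q(flags$node)),
      sprintf("flagWeight(%s,%d).", q(flags$node),
              .scale_weight(flags$residual_weight)))
  if (length(always_consistent))
    out <- c(out,
      "% collapsed positive cycles: internally explained",
      sprintf("consistent(%s).", q(always_consistent)))
  out <- c(out,
    "#minimize { 1@3,N : inconsistent(N) }.",
    "#minimize { 1@2,N : imperfect(N) }.",
    "#minimize { W@1,P,N : imperfectReg(P,N,W) }.",
    "#minimize { W@1,flag,N : flagWeight(N,W) }.")
  if (!is.null(fixed))
    out <- c(out, sprintf("color(%s,%s).", q(names(fixed)), fixed[[1L]]))
  out <- c(out, "#show color/2.")
  paste(out, collapse = "\n")
}

.enumerate_asp <- function(graph, fixed, flags,
                           always_consistent = character()) {
  clingo <- Sys.which("clingo")
  if (!nzchar(clingo))
    stop("asp backend requires an external 'clingo' solver on the PATH; ",
         "none was found (no silent fallback)", call. = FALSE)
  prog <- emit_asp_program(graph, fixed, flags, always_consistent)
  tf <- tempfile(fileext = ".lp")
  writeLines(prog, tf)
  on.exit(unlink(tf))
  raw <- suppressWarnings(
    system2(clingo, c("--opt-mode=optN", "--quiet=1", "0", tf),
            stdout = TRUE, stderr = TRUE))
  ans <- grep("^color\\(", raw, value = TRUE)
  if (!length(ans)) stop("clingo returned no optimal answer sets",
                         call. = FALSE)
  rows <- lapply(ans, function(line) {
    toks <- regmatches(line,
      gregexpr("color\\(\"([^\"]+)\",(up|down)\\)", line))[[1L]]
    nd <- sub("^color\\(\"([^\"]+)\".*$", "\\1", toks)
    sg <- sub("^.*,(up|down)\\)$", "\\1", toks)
    stats::setNames(sg, nd)[graph$nodes]
  })
  colorings <- do.call(rbind, rows)
  colnames(colorings) <- graph$nodes
  key <- apply(colorings, 1L, paste, collapse = "\r")
  colorings <- colorings[!duplicated(key), , drop = FALSE]
  obj3 <- .objective_matrix(graph, colorings == "up",
                            .normalize_flags(flags), always_consistent)
  list(colorings = colorings, obj = obj3[1L, ])
}
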