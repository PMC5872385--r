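# Independent brute-force oracle for the coloring objective, written as a
# plain per-target loop so it shares no code path with the package internals.

oracle_objective <- function(graph, coloring) {
  inc <- 0L; imp <- 0L; w <- 0
  for (t in unique(graph$edges$target)) {
    rows <- graph$edges[graph$edges$target == t, , drop = FALSE]
    explained <- FALSE; n_bad <- 0L; w_bad <- 0
    for (j in seq_len(nrow(rows))) {
      p <- coloring[[rows$source[j]]]
      ok <- if (rows$sign[j] == 1L) p == coloring[[t]] else p != coloring[[t]]
      if (ok) explained <- TRUE
      else { n_bad <- n_bad + 1L; w_bad <- w_bad + rows$weight[j] }
    }
    if (!explained) inc <- inc + 1L
    if (n_bad > 0L) imp <- imp + 1L
    w <- w + w_bad
  }
  c(inc, imp, w)
}

# all lexicographically optimal colorings by exhaustive scan of the 2^n space
oracle_optima <- function(graph) {
  nodes <- graph$nodes
  grid <- expand.grid(rep(list(c("down", "up")), length(nodes)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- nodes
  objs <- t(apply(grid, 1L, function(row)
    oracle_objective(graph, as.list(row))))
  best <- objs[order(objs[, 1L], objs[, 2L], objs[, 3L])[1L], ]
  keep <- objs[, 1L] == best[1L] & objs[, 2L] == best[2L] &
    abs(objs[, 3L] - best[3L]) < 1e-9
  m <- as.matrix(grid[keep, , drop = FALSE])
  m <- m[order(apply(m, 1L, paste, collapse = "\r")), , drop = FALSE]
  rownames(m) <- NULL
  list(colorings = m, objective = unname(best))
}

coloring_keys <- function(m) sort(apply(m, 1L, paste, collapse = "|"))

# corpus of random graphs shared by the oracle-equivalence and
# reduction-soundness suites
corpus_graph <- function(i) {
  set.seed(20000 + i)
  n <- if (i %% 20 == 0) 12L else sample(4:10, 1L)
  m <- sample(2:round(1.5 * n), 1L)
  random_signed_graph(n, m, p_inhibition = 0.4,
                      weight_range = if (i %% 2) c(1, 1) else c(1, 3),
                      seed = 20000 + i)
}

# reduced-graph enumeration with the bookkeeping perfect_coloring() uses
reduced_enumeration <- function(rg, backend = "bruteforce") {
  fs <- percolor:::.flag_split(rg)
  models <- enumerate_optimal(
    rg$graph, flags = fs$connected,
    always_consistent = intersect(rg$always_consistent, rg$graph$nodes),
    backend = backend)
  list(models = models, objective = models$objective + fs$offset)
}
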