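test_that("pairwise correlation classes follow the a/b counts", {
  rg <- reduce_all(toy_graph())
  red <- reduced_enumeration(rg)
  cm <- correlation_matrix(red$models)
  get <- function(x, y) cm$class[(cm$node1 == x & cm$node2 == y) |
                                   (cm$node1 == y & cm$node2 == x)]
  expect_equal(get("A", "G"), "negative")
  expect_equal(get("A", "B"), "positive")
  expect_equal(get("G", "H"), "positive")
  expect_true(all(cm$a + cm$b == nrow(red$models$colorings)))

  # a single model leaves no pair independent
  one <- red$models
  one$colorings <- one$colorings[1L, , drop = FALSE]
  expect_true(all(correlation_matrix(one)$class %in%
                    c("positive", "negative")))

  # four models realizing all sign combinations -> independent
  m <- structure(list(colorings = cbind(x = c("up", "up", "down", "down"),
                                        y = c("up", "down", "up", "down")),
                      objective = c(n_inconsistent = 0, n_imperfect = 0,
                                    imperfect_weight = 0),
                      fixed = NULL, free = character()),
                 class = "model_set")
  expect_equal(correlation_matrix(m)$class, "independent")
})

test_that("toy components match the narrated decomposition", {
  fit <- perfect_coloring(toy_graph())
  expect_length(fit$components, 2L)
  big <- fit$components[[which.max(lengths(lapply(fit$components,
                                                  `[[`, "members")))]]
  expect_equal(big$members,
               c(A = 1, B = 1, C = 1, D = 1, E = 1, F = 1, G = -1, H = -1))
  expect_equal(big$config1[["A"]], "up")        # canonical orientation
  expect_equal(big$config2[["A"]], "down")
  expect_equal(big$config1[["G"]], "down")
  small <- setdiff(seq_along(fit$components), which(vapply(
    fit$components, function(comp) "A" %in% names(comp$members), TRUE)))
  expect_equal(names(fit$components[[small]]$members), "I")
})

test_that("components partition the node set with coherent signs", {
  for (i in 1:15) {
    g <- corpus_graph(i)
    ms <- enumerate_optimal(g, backend = "bruteforce")
    comps <- identify_components(ms)
    members <- unlist(lapply(comps, function(comp) names(comp$members)))
    expect_setequal(members, g$nodes)
    expect_equal(anyDuplicated(members), 0L)
    # sign coherence: relative signs predict alike/opposite in every model
    for (comp in comps) {
      mem <- comp$members
      if (length(mem) < 2L) next
      sub <- ms$colorings[, names(mem), drop = FALSE]
      ref <- sub[, 1L] == "up"
      pred <- outer(ref, mem * mem[[1L]] > 0, function(r, s) r == s)
      expect_true(all((sub == "up") == pred))
    }
  }
})

test_that("component partition from reduced models equals full-graph one", {
  for (i in 1:12) {
    g <- corpus_graph(100 + i)
    full <- identify_components(enumerate_optimal(g, backend = "bruteforce"))
    rg <- reduce_all(g)
    red <- reduced_enumeration(rg)
    via_red <- identify_components(red$models, rg)
    key <- function(comps) sort(vapply(comps, function(comp)
      paste(names(comp$members), ifelse(comp$members > 0, "+", "-"),
            collapse = " ", sep = ""), ""))
    expect_equal(key(via_red), key(full))
  }
})

test_that("correlation is invariant under a global flip of the model set", {
  g <- corpus_graph(7)
  ms <- enumerate_optimal(g)
  flipped <- ms
  flipped$colorings <- ifelse(ms$colorings == "up", "down", "up")
  a <- correlation_matrix(ms); b <- correlation_matrix(flipped)
  expect_equal(a$class, b$class)
})

test_that("models agreeing everywhere give one spanning component", {
  chain <- signed_graph(data.frame(source = c("a", "b"), target = c("b", "c"),
                                   sign = 1L))
  comps <- identify_components(enumerate_optimal(chain))
  expect_length(comps, 1L)
  expect_equal(names(comps[[1]]$members), c("a", "b", "c"))
})
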