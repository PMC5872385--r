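test_that("the local explanation rule follows edge signs", {
  cases <- expand.grid(p = c("up", "down"), s = c(1L, -1L),
                       t = c("up", "down"), stringsAsFactors = FALSE)
  want <- with(cases, ifelse(s == 1L, p == t, p != t))
  expect_equal(explains(cases$p, cases$s, cases$t), want)
})

test_that("coloring evaluation scores the toy worked coloration", {
  g <- toy_graph()
  col1 <- c(A = "down", B = "down", C = "down", D = "down", E = "down",
            F = "down", G = "up", H = "up", I = "up")
  ev <- evaluate_coloring(g, col1)
  expect_equal(unname(ev$objective), c(0, 1, 1))
  imp <- ev$status[ev$status$imperfect, ]
  expect_equal(imp$node, "G")       # only G is imperfect, via one I -> G edge
  expect_equal(imp$imperfect_regulators[[1]]$source, "I")
  # its global reverse scores identically
  ev2 <- evaluate_coloring(g, ifelse(col1 == "up", "down", "up"))
  expect_equal(ev2$objective, ev$objective)
})

test_that("single-edge graphs score as the definitions force", {
  g <- signed_graph(data.frame(source = "A", target = "B", sign = 1L))
  expect_equal(unname(evaluate_coloring(g, c(A = "up", B = "up"))$objective),
               c(0, 0, 0))
  expect_equal(unname(evaluate_coloring(g, c(A = "up", B = "down"))$objective),
               c(1, 1, 1))
  expect_error(evaluate_coloring(g, c(A = "up")), "missing")
  expect_error(evaluate_coloring(g, c(A = "up", B = "sideways")),
               "'up' or 'down'")
})

test_that("objective matches the independent oracle on random colorings", {
  for (i in 1:15) {
    g <- random_signed_graph(7, 10, p_inhibition = 0.5, seed = 300 + i)
    set.seed(i)
    col <- setNames(sample(c("up", "down"), 7, replace = TRUE), g$nodes)
    expect_equal(unname(evaluate_coloring(g, col)$objective),
                 oracle_objective(g, as.list(col)))
  }
})

test_that("enumeration backends agree with the exhaustive oracle", {
  for (i in 1:12) {
    g <- random_signed_graph(sample(4:8, 1), sample(3:10, 1),
                             p_inhibition = 0.4, seed = 400 + i)
    orc <- oracle_optima(g)
    bf <- enumerate_optimal(g, backend = "bruteforce")
    bb <- enumerate_optimal(g, backend = "branchbound")
    expect_equal(coloring_keys(bf$colorings), coloring_keys(orc$colorings))
    expect_identical(bf$colorings, bb$colorings)
    expect_equal(unname(bf$objective), orc$objective)
    expect_equal(bf$objective, bb$objective)
  }
})

test_that("model sets are flip-closed when nothing is fixed", {
  for (i in 1:10) {
    g <- random_signed_graph(sample(4:9, 1), sample(3:12, 1),
                             p_inhibition = 0.5, seed = 500 + i)
    ms <- enumerate_optimal(g)
    flipped <- ifelse(ms$colorings == "up", "down", "up")
    expect_setequal(coloring_keys(ms$colorings), coloring_keys(flipped))
  }
})

test_that("fixing a node halves the set and flip completion restores it", {
  g <- toy_graph()
  free <- enumerate_optimal(g)
  fixed <- enumerate_optimal(g, fixed = c(A = "down"))
  expect_equal(nrow(fixed$colorings), nrow(free$colorings) / 2L)
  expect_true(all(fixed$colorings[, "A"] == "down"))
  expect_identical(flip_complete(fixed)$colorings, free$colorings)
  expect_equal(fixed$objective, free$objective)
})

test_that("stored objective is reproduced by re-evaluating returned models", {
  g <- random_signed_graph(8, 11, p_inhibition = 0.4, seed = 99)
  ms <- enumerate_optimal(g)
  for (r in seq_len(nrow(ms$colorings))) {
    ev <- evaluate_coloring(g, ms$colorings[r, ])
    expect_equal(ev$objective, ms$objective)
  }
})

test_that("free nodes are reported and double the model count", {
  g <- signed_graph(data.frame(source = "A", target = "B", sign = 1L),
                    nodes = c("A", "B", "Z"))
  ms <- enumerate_optimal(g)
  expect_equal(ms$free, "Z")
  expect_equal(nrow(ms$colorings), 4L)   # 2 consistent A/B states x 2 Z states
})

test_that("bruteforce refuses oversized graphs; asp errors without solver", {
  g <- random_signed_graph(25, 30, seed = 1)
  expect_error(enumerate_optimal(g, backend = "bruteforce", cap = 20L),
               "exceeds cap")
  if (!nzchar(Sys.which("clingo")))
    expect_error(enumerate_optimal(toy_graph(), backend = "asp"), "clingo")
})

test_that("degenerate and flagged inputs evaluate sanely", {
  # empty graph: one empty model
  ms <- enumerate_optimal(signed_graph())
  expect_equal(nrow(ms$colorings), 1L)
  expect_equal(unname(ms$objective), c(0, 0, 0))
  # flag forces consistent-and-imperfect with its residual weight
  g <- signed_graph(data.frame(source = "A", target = "B", sign = 1L))
  flags <- data.frame(node = "B", residual_weight = 2)
  ev <- evaluate_coloring(g, c(A = "up", B = "down"), flags = flags)
  expect_equal(unname(ev$objective), c(0, 1, 3))
  ev2 <- evaluate_coloring(g, c(A = "up", B = "up"), flags = flags)
  expect_equal(unname(ev2$objective), c(0, 1, 2))
})

test_that("the emitted ASP program encodes the full optimization", {
  txt <- emit_asp_program(toy_graph(), fixed = c(A = "down"),
                          flags = data.frame(node = "G",
                                             residual_weight = 1))
  expect_match(txt, "edge\\(\"B\",\"D\",1,1000000\\)")
  expect_match(txt, "1 \\{ color\\(X,S\\) : sign\\(S\\) \\} 1")
  expect_match(txt, "#minimize \\{ 1@3,N : inconsistent\\(N\\) \\}")
  expect_match(txt, "#minimize \\{ 1@2,N : imperfect\\(N\\) \\}")
  expect_match(txt, "W@1")
  expect_match(txt, "color\\(\"A\",down\\)")      # the fixing fact
  expect_match(txt, "consistent\\(\"G\"\\)")
  # empty graph still yields a well-formed program
  expect_match(emit_asp_program(signed_graph()), "#minimize")
})
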