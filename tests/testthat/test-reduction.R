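test_that("toy reduction proceeds exactly as narrated", {
  rg1 <- reduce_consistency(as_reduced_graph(toy_graph()))
  expect_setequal(names(which(lengths(c(rg1$subcomponents,
                                        rg1$isolated)) == 3L)), "D")
  expect_equal(rg1$subcomponents$D, c(D = 1, E = 1, F = 1))

  rg2 <- reduce_coregulators(rg1)
  expect_equal(rg2$subcomponents$B, c(B = 1, C = 1))

  rg3 <- reduce_edge_balance(rg2)
  expect_equal(names(rg3$isolated), "I")
  expect_equal(rg3$flags, data.frame(node = "G", residual_weight = 1))

  rg <- reduce_all(toy_graph())
  expect_setequal(names(rg$subcomponents), c("A", "B", "D", "G", "H"))
  expect_equal(names(rg$isolated), "I")
  expect_equal(lengths(rg$subcomponents)[c("A", "B", "D", "G", "H")],
               c(A = 1L, B = 2L, D = 3L, G = 1L, H = 1L))
})

test_that("consistency reduction composes signs along chains", {
  chain <- signed_graph(data.frame(source = c("a", "b"), target = c("b", "c"),
                                   sign = 1L))
  rg <- reduce_all(chain)
  expect_equal(c(rg$subcomponents, rg$isolated)$a, c(a = 1, b = 1, c = 1))

  inhib <- signed_graph(data.frame(source = "a", target = "b", sign = -1L))
  rg <- reduce_all(inhib)
  expect_equal(c(rg$subcomponents, rg$isolated)$a, c(a = 1, b = -1))

  # alternating chain: relative sign is the product along the path
  alt <- signed_graph(data.frame(source = c("a", "b", "c"),
                                 target = c("b", "c", "d"),
                                 sign = c(-1L, -1L, 1L)))
  rg <- reduce_all(alt)
  expect_equal(c(rg$subcomponents, rg$isolated)$a,
               c(a = 1, b = -1, c = 1, d = 1))
})

test_that("co-regulator merges respect the pattern's conditions", {
  # mixed-sign co-regulators merge with relative sign -1; oracle agrees that
  # every optimal model of the motif colors them oppositely
  motif <- signed_graph(data.frame(source = c("x", "y"), target = "z",
                                   sign = c(1L, -1L)))
  rg <- reduce_all(motif)
  expect_equal(c(rg$subcomponents, rg$isolated)$x[["y"]], -1)
  orc <- oracle_optima(motif)
  expect_true(all(orc$colorings[, "x"] != orc$colorings[, "y"]))

  # strict mode declines the mixed-sign pair
  rgs <- reduce_all(motif, strict_coregulators = TRUE)
  expect_equal(lengths(rgs$subcomponents), c(x = 1L, y = 1L, z = 1L))

  # a second successor disqualifies the pattern
  g2 <- signed_graph(data.frame(source = c("x", "y", "y"),
                                target = c("z", "z", "w"), sign = 1L))
  rg2 <- reduce_coregulators(as_reduced_graph(g2))
  expect_equal(lengths(rg2$subcomponents),
               c(w = 1L, x = 1L, y = 1L, z = 1L))
})

test_that("edge balance subtracts opposite weights and flags targets", {
  g <- signed_graph(data.frame(source = c("s", "s"), target = "t",
                               sign = c(1L, -1L), weight = c(3, 1)))
  rg <- reduce_all(g)
  expect_equal(rg$graph$edges$weight, 2)
  expect_equal(rg$graph$edges$sign, 1L)
  expect_equal(rg$flags, data.frame(node = "t", residual_weight = 1))

  # same-sign parallels merge by summation, no flag
  g2 <- signed_graph(data.frame(source = c("s", "s"), target = "t",
                                sign = 1L, weight = c(1, 2)))
  rg2 <- reduce_all(g2)
  expect_equal(nrow(rg2$flags), 0L)
  # same-sign aggregation happens at canonicalization already
  expect_equal(g2$edges$weight, 3)
})

test_that("reduction never grows the graph and terminates", {
  for (i in 1:25) {
    g <- corpus_graph(i)
    rg <- reduce_all(g)
    n_sub <- length(rg$subcomponents) + length(rg$isolated)
    expect_lte(n_sub, length(g$nodes))
    expect_lte(nrow(rg$graph$edges), nrow(g$edges))
    expect_setequal(unlist(lapply(c(rg$subcomponents, rg$isolated), names)),
                    g$nodes)
  }
})

test_that("expansion inverts merging", {
  rg <- reduce_all(toy_graph())
  col <- expand_coloring(rg, c(A = "down", B = "down", D = "down",
                               G = "up", H = "up", I = "up"))
  expect_equal(col, c(A = "down", B = "down", C = "down", D = "down",
                      E = "down", F = "down", G = "up", H = "up", I = "up"))
  sub <- reduce_all(signed_graph(data.frame(source = "a", target = "b",
                                            sign = -1L)))
  expect_equal(expand_coloring(sub, c(a = "up")), c(a = "up", b = "down"))
  expect_error(expand_coloring(rg, c(A = "down")), "cover")
  expect_error(expand_coloring(rg, c(Q = "down")), "unknown")
})

test_that("expand/restrict round-trips on enumerated toy models", {
  rg <- reduce_all(toy_graph())
  red <- reduced_enumeration(rg)
  for (r in seq_len(nrow(red$models$colorings))) {
    full <- expand_coloring(rg, c(red$models$colorings[r, ], I = "up"))
    back <- full[names(rg$subcomponents)]
    expect_equal(back, red$models$colorings[r, ])
  }
})

test_that("reductions preserve the optimum exactly on random graphs", {
  for (i in 1:40) {
    g <- corpus_graph(i)
    bf <- enumerate_optimal(g, backend = "bruteforce")
    for (variant in 1:2) {
      rg <- if (variant == 1L) reduce_all(g)
            else reduce_all(g, interleave = TRUE, rerun_after_balance = TRUE)
      red <- reduced_enumeration(rg)
      expect_equal(red$objective, bf$objective)
      expect_equal(coloring_keys(expand_models(rg, red$models)),
                   coloring_keys(bf$colorings))
    }
  }
})

test_that("negative cycles are left unmerged, positive cycles collapse", {
  # pure negative 2-cycle: no valid correlation, stays 2 nodes
  neg <- signed_graph(data.frame(source = c("x", "y"), target = c("y", "x"),
                                 sign = c(-1L, 1L)))
  rg <- reduce_all(neg)
  expect_equal(length(rg$subcomponents), 2L)
  red <- reduced_enumeration(rg)
  expect_equal(unname(red$objective), c(1, 1, 1))

  # pure positive 2-cycle collapses into one self-consistent subcomponent
  pos <- signed_graph(data.frame(source = c("x", "y"), target = c("y", "x"),
                                 sign = 1L))
  rgp <- reduce_all(pos)
  expect_equal(length(c(rgp$subcomponents, rgp$isolated)), 1L)
  orc <- oracle_optima(pos)
  expect_true(all(orc$colorings[, "x"] == orc$colorings[, "y"]))
})

test_that("relative-sign composition is associative across merge orders", {
  # a chain merged front-to-back or back-to-front yields the same partition
  g <- signed_graph(data.frame(source = c("a", "b", "c"),
                               target = c("b", "c", "d"),
                               sign = c(-1L, 1L, -1L)))
  rg <- reduce_all(g)
  mem <- c(rg$subcomponents, rg$isolated)[[1]]
  expect_equal(mem, c(a = 1, b = -1, c = -1, d = 1))
})
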