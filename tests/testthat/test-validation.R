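test_that("sign shuffling permutes labels but conserves counts", {
  obs <- new_discretized_profile(c(a = "up", b = "down", c = "up",
                                   d = "down", e = "up"))
  for (s in 1:10) {
    sh <- shuffle_signs(obs, seed = s)
    expect_setequal(names(sh$observations), names(obs$observations))
    expect_equal(sum(sh$observations == "up"), 3L)
    expect_identical(sh$observations,
                     shuffle_signs(obs, seed = s)$observations)
  }
  # all-up profile admits a single permutation
  allup <- new_discretized_profile(c(a = "up", b = "up"))
  expect_equal(shuffle_signs(allup, 3)$observations, allup$observations)
  # two-node mixed profile: both assignments occur, roughly equally
  two <- new_discretized_profile(c(x = "up", y = "down"))
  got <- vapply(1:200, function(s)
    shuffle_signs(two, s)$observations[["x"]], "")
  expect_setequal(unique(got), c("up", "down"))
  expect_gt(mean(got == "up"), 0.35)
  expect_lt(mean(got == "up"), 0.65)
})

test_that("welch_t matches the hand-computed Welch formula", {
  xs <- c(1, 2, 3); ys <- c(2, 3, 4)
  # independent oracle: direct formula evaluation
  sx <- var(xs) / 3; sy <- var(ys) / 3
  t_hand <- (mean(xs) - mean(ys)) / sqrt(sx + sy)
  df_hand <- (sx + sy)^2 / (sx^2 / 2 + sy^2 / 2)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  got <- welch_t(xs, ys)
  expect_equal(got$statistic, t_hand)
  expect_equal(got$df, df_hand)
  expect_equal(got$p.value, p_hand)
  # symmetry and degenerate cases
  swapped <- welch_t(ys, xs)
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p.value, got$p.value)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(welch_t(c(1, 1), c(1, 1))$p.value, 1)
})

test_that("clean profiles validate against shuffles, unseen ones do not", {
  chain <- signed_graph(data.frame(source = paste0("v", sprintf("%02d", 1:29)),
                                   target = paste0("v", sprintf("%02d", 2:30)),
                                   sign = rep_len(c(1L, -1L), 29)))
  fit <- perfect_coloring(chain)
  expect_length(fit$components, 1L)
  profs <- synthetic_profiles(fit$components, epsilon = 0.05,
                              n_samples = 8, seed = 3)
  rep <- validate_components(fit$components, profs, n_random = 5, seed = 9)
  expect_true(rep$applicable)
  expect_lt(rep$validation_p, 0.05)
  expect_equal(rep$n_random, 5L)

  # a component never observed is flagged not applicable
  other <- perfect_coloring(signed_graph(data.frame(
    source = "q1", target = "q2", sign = 1L)))$components
  rep2 <- validate_components(other, profs, seed = 9)
  expect_false(rep2$applicable)
  expect_true(is.na(rep2$validation_p))
  expect_error(validate_components(fit$components, profs[1]), "2 profiles")
})

test_that("specificity testing separates groups only when they differ", {
  chain <- signed_graph(data.frame(source = paste0("v", sprintf("%02d", 1:39)),
                                   target = paste0("v", sprintf("%02d", 2:40)),
                                   sign = rep_len(c(1L, -1L), 39)))
  fit <- perfect_coloring(chain)
  case <- synthetic_profiles(fit$components, epsilon = 0.35,
                             n_samples = 6, seed = 21)
  names(case) <- paste0("case", 1:6)
  ctrl <- synthetic_profiles(fit$components, epsilon = 0.02,
                             n_samples = 6, seed = 22)
  names(ctrl) <- paste0("ctrl", 1:6)
  for (i in seq_along(case)) case[[i]]$sample_id <- names(case)[i]
  for (i in seq_along(ctrl)) ctrl[[i]]$sample_id <- names(ctrl)[i]
  groups <- c(setNames(rep("case", 6), names(case)),
              setNames(rep("control", 6), names(ctrl)))
  rep <- validate_components(fit$components, c(case, ctrl), seed = 5,
                             groups = groups)
  expect_lt(rep$specificity_p, 0.05)
})

test_that("specificity p-values are calibrated under the null", {
  # identically distributed case/control groups: the fraction of p < 0.05
  # over repeated simulations stays within 3 SE of 0.05
  chain <- signed_graph(data.frame(source = paste0("v", sprintf("%02d", 1:29)),
                                   target = paste0("v", sprintf("%02d", 2:30)),
                                   sign = rep_len(c(1L, -1L), 29)))
  comp <- perfect_coloring(chain)$components[[1]]
  n_rep <- 400L
  set.seed(33)
  hits <- vapply(seq_len(n_rep), function(r) {
    profs <- synthetic_profiles(structure(list(comp), class = "component_set"),
                                epsilon = 0.25, n_samples = 12,
                                seed = 10000 + r)
    ms <- vapply(profs, function(p) maximal_similarity(comp, p)$ms, 0)
    welch_t(ms[1:6], ms[7:12])$p.value < 0.05
  }, TRUE)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(hits) - 0.05), 3 * se + 1e-12)
})
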