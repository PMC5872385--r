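#' Scramble the observed signs of a profile
#'
#' Permutes the up/down labels uniformly at random over the observed nodes.
#' The observed node set and the up/down counts are conserved exactly; only
#' the assignment of labels to nodes changes.
#'
#' @param obs a \code{discretized_profile}.
#' @param seed integer seed (deterministic output).
#' @return a \code{discretized_profile}.
#' @export
shuffle_signs <- function(obs, seed) {
  stopifnot(inherits(obs, "discretized_profile"))
  o <- obs$observations
  shuffled <- with_seed(seed, sample(unname(o)))
  new_discretized_profile(stats::setNames(shuffled, names(o)),
                          sample_id = obs$sample_id, fold = obs$fold)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom (a thin
#' wrapper around [stats::t.test()] with \code{var.equal = FALSE}).  Errors on
#' degenerate inputs: either sample smaller than 2, or both samples with zero
#' variance.
#'
#' @param xs,ys numeric vectors.
#' @return list with \code{statistic}, \code{df} and \code{p.value}.
#' @export
welch_t <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) < 2L || length(ys) < 2L)
    stop("welch_t needs at least 2 observations per sample", call. = FALSE)
  if (stats::var(xs) == 0 && stats::var(ys) == 0) {
    if (isTRUE(all.equal(mean(xs), mean(ys))))
      return(list(statistic = 0, df = length(xs) + length(ys) - 2,
                  p.value = 1))
    stop("welch_t: both samples have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(xs, ys, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Randomization validation and case/control specificity of components
#'
#' For each component, the maximal-similarity values over the real profiles
#' are compared (Welch's t-test, two-sided) with the MS values over
#' \code{n_random} sign-scrambled copies of every profile pooled into one
#' comparison sample (\code{validation_p}).  When a case/control grouping is
#' supplied, case-profile MS values are additionally compared with
#' control-profile MS values (\code{specificity_p}).
#'
#' @param components a \code{component_set}.
#' @param profiles named list of \code{discretized_profile} objects (>= 2).
#' @param n_random randomized copies per profile (default 5).
#' @param seed integer seed driving all shuffles.
#' @param groups optional named character vector sample ->
#'   \code{case}/\code{control}; names must match profile names.
#' @return data frame with one row per component: \code{component},
#'   \code{n_nodes}, \code{n_observed_mean}, \code{validation_p},
#'   \code{specificity_p}, \code{n_random}, \code{seed}, \code{applicable}.
#' @export
validate_components <- function(components, profiles, n_random = 5L,
                                seed = 1L, groups = NULL) {
  stopifnot(inherits(components, "component_set"))
  if (length(profiles) < 2L)
    stop("need at least 2 profiles", call. = FALSE)
  shuffled <- with_seed(seed, {
    lapply(profiles, function(p)
      lapply(seq_len(n_random), function(r)
        shuffle_signs(p, sample.int(.Machine$integer.max, 1L))))
  })
  rows <- lapply(components, function(comp) {
    real <- vapply(profiles, function(p)
      maximal_similarity(comp, p)$ms, 0)
    rand <- unlist(lapply(shuffled, function(ps)
      vapply(ps, function(p) maximal_similarity(comp, p)$ms, 0)))
    ok_real <- real[!is.na(real)]
    ok_rand <- rand[!is.na(rand)]
    applicable <- length(ok_real) >= 2L && length(ok_rand) >= 2L
    vp <- NA_real_
    if (applicable)
      vp <- tryCatch(welch_t(ok_real, ok_rand)$p.value,
                     error = function(e) NA_real_)
    sp <- NA_real_
    if (!is.null(groups)) {
      cs <- real[names(profiles) %in% names(groups)[groups == "case"]]
      ct <- real[names(profiles) %in% names(groups)[groups == "control"]]
      cs <- cs[!is.na(cs)]; ct <- ct[!is.na(ct)]
      if (length(cs) >= 2L && length(ct) >= 2L)
        sp <- tryCatch(welch_t(cs, ct)$p.value, error = function(e) NA_real_)
    }
    data.frame(component = comp$id, n_nodes = length(comp$members),
               n_observed_mean = mean(vapply(profiles, function(p)
                 maximal_similarity(comp, p)$n_observed, 0L)),
               validation_p = vp, specificity_p = sp,
               n_random = as.integer(n_random), seed = as.integer(seed),
               applicable = applicable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
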