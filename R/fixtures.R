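#' The 9-node toy signaling graph
#'
#' A small influence graph (9 molecular-species nodes A-I, 11 unit-weight
#' edges) exercising every stage of the framework: the consistency reduction
#' merges D, E and F; the co-regulator reduction merges B and C; the
#' edge-balance reduction cancels the two opposite-signed I -> G edges,
#' isolating I and flagging G as always-consistent / always-imperfect; the
#' reduced connected part admits exactly two optimal colorings (global
#' reverses of each other), and component identification yields two
#' components, \{A+, B+, C+, D+, E+, F+, G-, H-\} and \{I\}.
#'
#' The edge list is a reconstruction constrained by those narrated behaviors
#' (the original figure is graphical); every toy-based test asserts the
#' behaviors, not the private edge list.
#'
#' @return a [signed_graph()].
#' @export
toy_graph <- function() {
  signed_graph(data.frame(
    source = c("B", "C", "D", "D", "G", "I", "F", "D", "G", "H", "I"),
    sign   = c( 1L,  1L,  1L,  1L,  1L,  1L, -1L, -1L, -1L, -1L, -1L),
    target = c("D", "D", "E", "F", "H", "G", "G", "H", "A", "A", "G"),
    weight = 1, stringsAsFactors = FALSE))
}

#' The worked toy observation profile
#'
#' The three-gene discretized profile \{D: up, E: up, G: up\} used in the
#' worked maximal-similarity example (Sim_C1 = 2, Sim_C2 = 1, MS = 2/3
#' against the large toy component).
#'
#' @return a \code{discretized_profile}.
#' @export
toy_profile <- function() {
  new_discretized_profile(c(D = "up", E = "up", G = "up"),
                          sample_id = "toy")
}

#' Random signed directed graph
#'
#' Simple directed graph (no self-loops, no duplicate ordered pairs) with
#' uniformly sampled edges, Bernoulli(\code{p_inhibition}) inhibition signs
#' and integer weights uniform over \code{weight_range}.  Deterministic given
#' \code{seed}.
#'
#' @param n_nodes,n_edges graph size; \code{n_edges} at most
#'   \code{n_nodes * (n_nodes - 1)}.
#' @param p_inhibition probability an edge is an inhibition.
#' @param weight_range integer range \code{c(lo, hi)} for edge weights.
#' @param seed integer seed.
#' @return a [signed_graph()].
#' @export
random_signed_graph <- function(n_nodes, n_edges, p_inhibition = 0.3,
                                weight_range = c(1, 1), seed = 1L) {
  if (n_edges > n_nodes * (n_nodes - 1L))
    stop("n_edges exceeds the number of ordered node pairs", call. = FALSE)
  if (p_inhibition < 0 || p_inhibition > 1)
    stop("p_inhibition must be in [0, 1]", call. = FALSE)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  with_seed(seed, {
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    sgn <- ifelse(stats::runif(n_edges) < p_inhibition, -1L, 1L)
    w <- if (weight_range[1L] == weight_range[2L]) rep(weight_range[1L], n_edges)
         else sample(seq(weight_range[1L], weight_range[2L]), n_edges,
                     replace = TRUE)
    g <- if (n_edges > 0)
      signed_graph(data.frame(source = pick$source, target = pick$target,
                              sign = sgn, weight = w,
                              stringsAsFactors = FALSE), nodes = nodes)
    else signed_graph(nodes = nodes)
    g
  })
}

#' Synthetic discretized profiles from component configurations
#'
#' Emulates the discrete observation model of the framework: each sample
#' observes each member of each component with probability
#' \code{1 - unobserved_rate}, and each observed sign equals the chosen
#' configuration's sign flipped independently with probability \code{epsilon}.
#' Noise is sign-flip (discrete), matching the up/down observation space,
#' not Gaussian expression noise.
#'
#' @param components a \code{component_set}.
#' @param config which configuration generates the data: \code{1} or
#'   \code{2}, recycled over components.
#' @param epsilon sign-flip noise rate in [0, 1/2).
#' @param unobserved_rate per-node dropout probability in [0, 1).
#' @param n_samples number of profiles.
#' @param seed integer seed.
#' @return named list of \code{discretized_profile} objects.
#' @export
synthetic_profiles <- function(components, config = 1L, epsilon = 0.1,
                               unobserved_rate = 0, n_samples = 1L,
                               seed = 1L) {
  stopifnot(inherits(components, "component_set"))
  if (epsilon < 0 || epsilon >= 0.5)
    stop("epsilon must be in [0, 1/2)", call. = FALSE)
  if (unobserved_rate < 0 || unobserved_rate >= 1)
    stop("unobserved_rate must be in [0, 1)", call. = FALSE)
  config <- rep_len(config, length(components))
  truth <- unlist(lapply(seq_along(components), function(i) {
    comp <- components[[i]]
    if (config[i] == 1L) comp$config1 else comp$config2
  }))
  with_seed(seed, {
    out <- lapply(seq_len(n_samples), function(s) {
      keep <- stats::runif(length(truth)) >= unobserved_rate
      obs <- truth[keep]
      flip <- stats::runif(length(obs)) < epsilon
      obs[flip] <- .flip_sign(obs[flip])
      new_discretized_profile(obs, sample_id = sprintf("synth%03d", s))
    })
    stats::setNames(out, vapply(out, function(p) p$sample_id, ""))
  })
}
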