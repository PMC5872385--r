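#' Perfect-coloring analysis of a signed graph
#'
#' The central fitting function of the package.  It reduces the graph
#' (consistency, co-regulator and edge-balance reductions), enumerates the
#' complete set of colorings of the reduced connected part that
#' lexicographically minimize (inconsistent targets, imperfect targets,
#' imperfect-regulator weight), and derives the color-correlated components
#' with their two mutually-reversed configurations.
#'
#' With \code{fix = "auto"} (default) the search space is halved by pinning
#' the lexicographically smallest node of the largest connected part of the
#' reduced graph to \code{"down"}; the global-flip closure is restored before
#' component correlation, so the reported model set and components are
#' identical to an unfixed run.
#'
#' @param graph a [signed_graph()] (or a path to an edge-list file).
#' @param fix \code{"auto"}, \code{"none"}, or a single named
#'   \code{up}/\code{down} vector.
#' @param backend solver backend, see [enumerate_optimal()].
#' @param strict_coregulators,interleave,rerun_after_balance
#'   see [reduce_all()].
#' @param cap bruteforce node cap.
#' @return an object of class \code{perfect_coloring}: list with
#'   \code{graph}, \code{reduced} ([reduce_all()] result), \code{models}
#'   (flip-completed \code{model_set} over the reduced connected part),
#'   \code{objective} (the optimum triple, including the constant
#'   contribution of isolated flagged targets), \code{components}
#'   (a \code{component_set} over original node ids) and \code{fix}.
#' @examples
#' fit <- perfect_coloring(toy_graph())
#' fit
#' summary(fit)
#' maximal_similarity(fit$components[[1]], toy_profile())
#' @export
perfect_coloring <- function(graph, fix = "auto",
                             backend = c("branchbound", "bruteforce", "asp"),
                             strict_coregulators = FALSE, interleave = FALSE,
                             rerun_after_balance = FALSE, cap = 20L) {
  backend <- match.arg(backend)
  if (is.character(graph) && length(graph) == 1L)
    graph <- read_signed_graph(graph)
  stopifnot(inherits(graph, "signed_graph"))
  rg <- reduce_all(graph, strict_coregulators = strict_coregulators,
                   interleave = interleave,
                   rerun_after_balance = rerun_after_balance)
  fs <- .flag_split(rg)
  fixed <- NULL
  if (identical(fix, "auto")) {
    fixed <- .auto_fix(rg)
  } else if (!identical(fix, "none") && !is.null(fix)) {
    fixed <- fix
  }
  models <- enumerate_optimal(rg$graph, fixed = fixed,
                              flags = fs$connected,
                              always_consistent =
                                intersect(rg$always_consistent,
                                          rg$graph$nodes),
                              backend = backend, cap = cap)
  if (!is.null(fixed)) models <- flip_complete(models)
  objective <- models$objective + fs$offset
  components <- identify_components(models, rg)
  structure(list(graph = graph, reduced = rg, models = models,
                 objective = objective, components = components,
                 fix = fixed, backend = backend),
            class = "perfect_coloring")
}

# lexicographically smallest node of the largest weakly connected part of the
# reduced graph, fixed down; NULL when the reduced graph has no nodes
.auto_fix <- function(rg) {
  g <- rg$graph
  if (length(g$nodes) == 0L) return(NULL)
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = g$nodes))
  comp <- igraph::components(ig, mode = "weak")
  biggest <- which.max(comp$csize)
  members <- names(comp$membership)[comp$membership == biggest]
  stats::setNames("down", min(members))
}

#' @export
print.perfect_coloring <- function(x, ...) {
  cat("perfect coloring analysis\n")
  print(x$graph)
  cat(sprintf("reduced to %d subcomponent(s) + %d isolated; %d optimal coloring(s)\n",
              length(x$reduced$subcomponents), length(x$reduced$isolated),
              nrow(x$models$colorings)))
  cat(sprintf("objective: %d inconsistent, %d imperfect, weight %s\n",
              x$objective[["n_inconsistent"]], x$objective[["n_imperfect"]],
              format(x$objective[["imperfect_weight"]])))
  cat(sprintf("%d component(s)\n", length(x$components)))
  invisible(x)
}

#' @export
summary.perfect_coloring <- function(object, ...) {
  g <- object$graph
  s <- list(
    n_nodes = length(g$nodes),
    n_targets = length(target_nodes(g)),
    n_edges = nrow(g$edges),
    n_subcomponents = length(object$reduced$subcomponents),
    n_isolated = length(object$reduced$isolated),
    n_reduced_edges = nrow(object$reduced$graph$edges),
    n_models = nrow(object$models$colorings),
    n_inconsistent = unname(object$objective[["n_inconsistent"]]),
    n_imperfect = unname(object$objective[["n_imperfect"]]),
    imperfect_weight = unname(object$objective[["imperfect_weight"]]),
    n_components = length(object$components),
    component_sizes = vapply(object$components,
                             function(comp) length(comp$members), 0L))
  class(s) <- "summary.perfect_coloring"
  s
}

#' @export
print.summary.perfect_coloring <- function(x, ...) {
  cat(sprintf("nodes: %d  targets: %d  edges: %d\n", x$n_nodes, x$n_targets,
              x$n_edges))
  cat(sprintf("reduced: %d subcomponents (+%d isolated), %d edges\n",
              x$n_subcomponents, x$n_isolated, x$n_reduced_edges))
  cat(sprintf("optimal colorings: %d  objective: (%d, %d, %s)\n",
              x$n_models, x$n_inconsistent, x$n_imperfect,
              format(x$imperfect_weight)))
  cat(sprintf("components: %d (sizes: %s)\n", x$n_components,
              paste(sort(x$component_sizes, decreasing = TRUE),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.perfect_coloring <- function(x, ...) {
  g <- x$graph
  comp_of <- stats::setNames(
    rep(seq_along(x$components),
        vapply(x$components, function(comp) length(comp$members), 0L)),
    unlist(lapply(x$components, function(comp) names(comp$members))))
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = g$nodes))
  pal <- grDevices::hcl.colors(max(comp_of), "Dynamic")
  igraph::plot.igraph(
    ig, vertex.color = pal[comp_of[g$nodes]],
    edge.color = ifelse(g$edges$sign == 1L, "grey30", "firebrick"),
    edge.arrow.size = 0.4, ...)
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole workflow in its canonical order -- reduction and
#' coloring strictly before any confrontation with expression data -- then
#' scores components against the supplied profiles (maximal similarity) and
#' validates them by sign randomization, writing all artifacts under
#' \code{out_dir} when given.  The coloring stages never see the expression
#' inputs, so the model set and components are identical whether or not
#' profiles are supplied.
#'
#' @param graph a [signed_graph()] or edge-list path.
#' @param profiles optional named list of \code{discretized_profile}s, or a
#'   list \code{list(matrix = <path/matrix>, groups = <path/named vector>)}
#'   to be discretized here.
#' @param fold fold-change discretization threshold (default 1.2).
#' @param n_random randomized datasets per profile for validation (default 5).
#' @param seed root seed for every randomized step.
#' @param groups optional named sample -> case/control vector (derived from
#'   \code{profiles$groups} when discretizing here).
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @inheritParams perfect_coloring
#' @return a list of class \code{percolor_run}: \code{fit}
#'   (the [perfect_coloring()] object), \code{ms} (similarity table or NULL),
#'   \code{validation} (report or NULL) and \code{summary} (named list).
#' @export
run_pipeline <- function(graph, profiles = NULL, fold = 1.2, n_random = 5L,
                         seed = 1L, groups = NULL, out_dir = NULL,
                         fix = "auto",
                         backend = c("branchbound", "bruteforce", "asp"),
                         strict_coregulators = FALSE, interleave = FALSE,
                         rerun_after_balance = FALSE, cap = 20L) {
  backend <- match.arg(backend)
  fit <- perfect_coloring(graph, fix = fix, backend = backend,
                          strict_coregulators = strict_coregulators,
                          interleave = interleave,
                          rerun_after_balance = rerun_after_balance,
                          cap = cap)
  if (!is.null(profiles) && !is.null(profiles$matrix)) {
    mat <- profiles$matrix
    if (is.character(mat)) mat <- read_expression_matrix(mat)
    grp <- profiles$groups
    if (is.character(grp) && length(grp) == 1L && file.exists(grp))
      grp <- read_sample_groups(grp)
    groups <- grp
    profiles <- discretize_matrix(mat, grp, fold = fold)
  }
  ms <- NULL
  validation <- NULL
  if (!is.null(profiles) && length(profiles)) {
    ms <- similarity_table(fit$components, profiles)
    if (length(profiles) >= 2L)
      validation <- validate_components(fit$components, profiles,
                                        n_random = n_random, seed = seed,
                                        groups = groups)
  }
  smry <- summary(fit)
  run_summary <- c(unclass(smry)[c("n_nodes", "n_targets", "n_edges",
                                   "n_subcomponents", "n_isolated",
                                   "n_reduced_edges", "n_models",
                                   "n_inconsistent", "n_imperfect",
                                   "imperfect_weight", "n_components")],
                   list(component_sizes = unname(smry$component_sizes),
                        n_profiles = length(profiles), fold = fold,
                        n_random = as.integer(n_random),
                        seed = as.integer(seed), backend = backend,
                        fixed = if (is.null(fit$fix)) NULL
                                else list(node = names(fit$fix),
                                          sign = unname(fit$fix))))
  out <- structure(list(fit = fit, ms = ms, validation = validation,
                        summary = run_summary), class = "percolor_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reduced_graph(fit$reduced, file.path(out_dir, "reduced"))
    write_model_set(fit$models, file.path(out_dir, "models.tsv"))
    write_components(fit$components, file.path(out_dir, "components.tsv"))
    if (!is.null(ms))
      utils::write.table(ms, file.path(out_dir, "similarity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(validation))
      utils::write.table(validation, file.path(out_dir, "validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(run_summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.percolor_run <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ms))
    cat(sprintf("similarity table: %d rows over %d profile(s)\n",
                nrow(x$ms), x$summary$n_profiles))
  if (!is.null(x$validation))
    cat(sprintf("validation report: %d component(s)\n", nrow(x$validation)))
  invisible(x)
}
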