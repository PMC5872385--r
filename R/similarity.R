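#' Discretize an expression profile against control means
#'
#' A gene is called \code{up} when its value is at least \code{fold} times
#' the control mean, \code{down} when it is at most the control mean divided
#' by \code{fold}, and left unobserved inside the band.  Comparisons are on
#' the raw scale by default (set \code{log2_scale = TRUE} for log2-transformed
#' matrices, where the band becomes +/- log2(fold) around the control mean).
#' Both boundaries are inclusive, which keeps the discretizer monotone in the
#' measured value.
#'
#' @param profile named numeric vector, gene id -> expression value.
#' @param control_means named numeric vector, gene id -> control mean; genes
#'   with non-positive control means are skipped with a warning (raw scale
#'   only).
#' @param fold fold-change threshold (> 1); default 1.2.
#' @param sample_id identifier stored with the profile.
#' @param log2_scale interpret values as log2 expression.
#' @return an object of class \code{discretized_profile}: a list with
#'   \code{observations} (named \code{up}/\code{down} vector over observed
#'   genes), \code{sample_id} and \code{fold}.
#' @export
discretize <- function(profile, control_means, fold = 1.2,
                       sample_id = NA_character_, log2_scale = FALSE) {
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 1)
    stop("`fold` must be a single number > 1", call. = FALSE)
  genes <- intersect(names(profile), names(control_means))
  v <- profile[genes]
  mu <- control_means[genes]
  if (!log2_scale) {
    bad <- !is.finite(mu) | mu <= 0
    if (any(bad)) {
      warning(sum(bad), " gene(s) skipped: non-positive control mean",
              call. = FALSE)
      genes <- genes[!bad]; v <- v[!bad]; mu <- mu[!bad]
    }
    up <- v >= fold * mu
    down <- v <= mu / fold
  } else {
    up <- v >= mu + log2(fold)
    down <- v <= mu - log2(fold)
  }
  obs <- character(0)
  if (length(genes))
    obs <- stats::setNames(ifelse(up, "up", ifelse(down, "down", NA)), genes)
  obs <- obs[!is.na(obs)]
  new_discretized_profile(obs, sample_id = sample_id, fold = fold)
}

#' Construct a discretized profile directly
#'
#' @param observations named \code{up}/\code{down} character vector.
#' @param sample_id sample identifier.
#' @param fold fold threshold recorded with the profile (NA when the profile
#'   was not derived from continuous values).
#' @return a \code{discretized_profile}.
#' @export
new_discretized_profile <- function(observations, sample_id = NA_character_,
                                    fold = NA_real_) {
  observations <- unlist(observations)
  if (length(observations) && (!all(observations %in% c("up", "down")) ||
                               is.null(names(observations))))
    stop("observations must be a named 'up'/'down' vector", call. = FALSE)
  if (!length(observations))
    observations <- stats::setNames(character(0), character(0))
  structure(list(observations = observations[order(names(observations))],
                 sample_id = sample_id, fold = fold),
            class = "discretized_profile")
}

#' @export
print.discretized_profile <- function(x, ...) {
  cat(sprintf("discretized profile%s: %d observed (%d up, %d down)\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              length(x$observations), sum(x$observations == "up"),
              sum(x$observations == "down")))
  invisible(x)
}

#' Discretize every sample of an expression matrix
#'
#' Control means are taken over the columns labelled \code{control} in
#' \code{groups}; every other sample is discretized against them.
#'
#' @param mat numeric matrix, genes x samples.
#' @param groups named character vector sample -> \code{case}/\code{control}.
#' @param fold fold-change threshold.
#' @param include_controls also discretize the control samples (against the
#'   control mean); default TRUE, as control profiles are needed for
#'   specificity testing.
#' @inheritParams discretize
#' @return named list of \code{discretized_profile} objects.
#' @export
discretize_matrix <- function(mat, groups, fold = 1.2,
                              include_controls = TRUE, log2_scale = FALSE) {
  ctrl <- names(groups)[groups == "control"]
  ctrl <- intersect(ctrl, colnames(mat))
  if (!length(ctrl)) stop("no control samples found", call. = FALSE)
  mu <- rowMeans(mat[, ctrl, drop = FALSE])
  samples <- colnames(mat)
  if (!include_controls) samples <- setdiff(samples, ctrl)
  out <- lapply(samples, function(s)
    discretize(mat[, s], mu, fold = fold, sample_id = s,
               log2_scale = log2_scale))
  stats::setNames(out, samples)
}

#' Maximal similarity between a component and an observation profile
#'
#' A component has exactly two mutually-reversed sign configurations.  The
#' maximal similarity is the larger of the two agreement counts between the
#' observed signs (restricted to component members) and each configuration,
#' divided by the number of observed members: \code{MS = max(k, n - k) / n},
#' where \code{k} counts agreements with \code{config1}.  MS always lies in
#' [1/2, 1]; it is undefined (NA) when no member is observed.
#'
#' @param component one element of a \code{component_set}.
#' @param obs a \code{discretized_profile} (or named \code{up}/\code{down}
#'   vector).
#' @return a one-row data frame (class \code{ms_record}): \code{component},
#'   \code{sample}, \code{n_observed}, \code{sim_c1}, \code{sim_c2},
#'   \code{ms}.
#' @export
maximal_similarity <- function(component, obs) {
  sample_id <- NA_character_
  if (inherits(obs, "discretized_profile")) {
    sample_id <- obs$sample_id
    obs <- obs$observations
  }
  seen <- intersect(names(obs), names(component$members))
  n <- length(seen)
  k <- if (n) sum(obs[seen] == component$config1[seen]) else 0L
  data.frame(component = component$id, sample = sample_id, n_observed = n,
             sim_c1 = k, sim_c2 = n - k,
             ms = if (n) max(k, n - k) / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Maximal-similarity table over components and profiles
#'
#' @param components a \code{component_set}.
#' @param profiles list of \code{discretized_profile} objects.
#' @return data frame with one row per (component, profile).
#' @export
similarity_table <- function(components, profiles) {
  do.call(rbind, lapply(profiles, function(p)
    do.call(rbind, lapply(components, maximal_similarity, obs = p))))
}
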