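#' Specification of an N-way K-shot task
#'
#' @param n_way number of classes per episode (>= 2).
#' @param k_shot labelled support samples per class (>= 1).
#' @param query_per_class query samples requested per class (>= 1); clipped
#'   by availability for small classes.
#' @return list of class `episode_spec`.
#' @export
episode_spec <- function(n_way = 4L, k_shot = 1L, query_per_class = 20L) {
  n_way <- as.integer(n_way); k_shot <- as.integer(k_shot)
  query_per_class <- as.integer(query_per_class)
  if (n_way < 2L) stop("n_way must be >= 2")
  if (k_shot < 1L) stop("k_shot must be >= 1")
  if (query_per_class < 1L) stop("query_per_class must be >= 1")
  structure(list(n_way = n_way, k_shot = k_shot,
                 query_per_class = query_per_class),
            class = "episode_spec")
}

#' Sample one episode from a dataset bundle
#'
#' Draws `n_way` classes, then per class `k_shot` support samples without
#' replacement and up to `query_per_class` further samples (disjoint from the
#' support set) as queries. Classes with fewer than `k_shot + 1` samples are
#' not eligible. Small classes simply contribute fewer queries, so unequal
#' class sizes are handled without replacement sampling.
#'
#' @param bundle a [dataset_bundle].
#' @param spec an [episode_spec].
#' @param seed optional integer; when given the episode is drawn from a
#'   private RNG stream and the caller's RNG state is untouched.
#' @return list of class `episode` with `support` (list of `n_way` lists of
#'   `k_shot` samples), `query` (flat sample list), `query_labels`, and
#'   `class_order` (the selected class names, support order).
#' @export
sample_episode <- function(bundle, spec, seed = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"), inherits(spec, "episode_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  labels <- bundle_labels(bundle)
  counts <- table(labels)
  eligible <- names(counts)[counts >= spec$k_shot + 1L]
  if (length(eligible) < spec$n_way)
    stop("bundle has ", length(eligible), " classes with >= k_shot + 1 ",
         "samples; need ", spec$n_way)
  class_order <- sample(eligible, spec$n_way)
  support <- vector("list", spec$n_way)
  query <- list(); query_labels <- character(0)
  for (i in seq_len(spec$n_way)) {
    idx <- which(labels == class_order[i])
    sup_idx <- sample(idx, spec$k_shot)
    rest <- setdiff(idx, sup_idx)
    q_idx <- sample(rest, min(spec$query_per_class, length(rest)))
    support[[i]] <- bundle$samples[sup_idx]
    query <- c(query, bundle$samples[q_idx])
    query_labels <- c(query_labels, rep(class_order[i], length(q_idx)))
  }
  structure(list(support = support, query = query,
                 query_labels = query_labels, class_order = class_order,
                 spec = spec),
            class = "episode")
}

#' Relation-label targets for an episode
#'
#' The `[n_way x n_query]` 0/1 matrix whose entry `(i, j)` is 1 exactly when
#' query `j` belongs to the episode's `i`-th class: the regression target for
#' the relation scores. Every column sums to 1.
#'
#' @param episode an episode from [sample_episode()].
#' @return numeric 0/1 matrix `[n_way x n_query]`.
#' @export
relation_targets <- function(episode) {
  stopifnot(inherits(episode, "episode"))
  outer(episode$class_order, episode$query_labels, "==") * 1
}
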