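# broom-style accessors for the pipeline's fitted objects.

#' Tidy a profile clustering
#'
#' @param x A `profile_clusters` object.
#' @param ... Unused.
#' @return Tibble with one row per gene: `gene`, `cluster`.
#' @exportS3Method generics::tidy
tidy.profile_clusters <- function(x, ...) x$assignment

#' @rdname tidy.profile_clusters
#' @return For `glance()`: a one-row tibble with `k`, `wcss`, `n_iter_run`,
#'   `restarts`, `seed`.
#' @exportS3Method generics::glance
glance.profile_clusters <- function(x, ...) {
  tibble(k = x$k, wcss = x$wcss, n_iter_run = x$n_iter_run,
         restarts = x$restarts, seed = x$seed)
}

#' Tidy an enrichment map
#'
#' @param x An `enrichment_map`.
#' @param what `"nodes"` (default) or `"edges"`.
#' @param ... Unused.
#' @return The node or edge tibble.
#' @exportS3Method generics::tidy
tidy.enrichment_map <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @rdname tidy.enrichment_map
#' @return For `glance()`: one-row tibble with `n_nodes`, `n_edges`,
#'   `n_components`, `edge_threshold`.
#' @exportS3Method generics::glance
glance.enrichment_map <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_components = length(unique(x$nodes$component)),
         edge_threshold = x$edge_threshold)
}

#' Tidy a full pipeline run
#'
#' @param x A `training_map_analysis`.
#' @param ... Unused.
#' @return The per-gene differential table with a `responder` flag.
#' @exportS3Method generics::tidy
tidy.training_map_analysis <- function(x, ...) x$differential

#' @rdname tidy.training_map_analysis
#' @return For `glance()`: one-row tibble summarizing the run.
#' @exportS3Method generics::glance
glance.training_map_analysis <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_genes = nrow(x$differential),
           n_responders = length(x$responders),
           n_sets_tested = nrow(x$enrichment),
           n_sets_significant = sum(x$enrichment$significant)),
    glance(x$map)
  )
}
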