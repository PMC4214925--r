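#' Run the full training-response enrichment-map pipeline
#'
#' Chains the stages end to end: quantile normalization, response/SNR
#' profiling, k-means clustering of profiles, per-gene factorial interaction
#' tests with BH adjustment within clusters, responder selection (stronger
#' trainer than comparator response), hypergeometric gene-set enrichment of
#' the responders against the merged collections, and construction of the
#' overlap-scored enrichment map with Tarjan component labels.
#'
#' @param es An [expression_set()].
#' @param gene_sets Gene-set tibble ([read_gmt()] layout); several
#'   collections may be combined with `dplyr::bind_rows()` since set names
#'   carry their source tag.
#' @param k,seed,restarts Passed to [cluster_profiles()].
#' @param alpha,per_cluster Passed to [differential_test()].
#' @param score_threshold,min_set_size,max_set_size,use_adjusted Passed to
#'   [enrich()].
#' @param edge_threshold Passed to [build_enrichment_map()].
#' @param normalize Quantile-normalize before profiling (default TRUE).
#' @return An object of class `training_map_analysis`: list with the
#'   normalized `expression`, `profiles`, `clusters`, `differential`,
#'   `responders`, `enrichment` and `map`.
#' @export
#'
#' @examples
#' sim <- simulate_training_experiment(n_genes = 400, n_responders = 60,
#'                                     n_decoy_sets = 10, seed = 3)
#' res <- build_training_map(sim$expression, sim$gene_sets, k = 3)
#' res$map
build_training_map <- function(es, gene_sets,
                               k = 9, seed = 17, restarts = 10,
                               alpha = 0.05, per_cluster = TRUE,
                               score_threshold = 1.3,
                               min_set_size = 5, max_set_size = 500,
                               use_adjusted = FALSE,
                               edge_threshold = 0.25,
                               normalize = TRUE) {
  if (normalize) es <- quantile_normalize(es)
  profiles <- response_profiles(es)
  clusters <- cluster_profiles(profiles, k = k, seed = seed, restarts = restarts)
  differential <- differential_test(es, clusters, alpha = alpha,
                                    per_cluster = per_cluster)
  responders <- differential$gene[differential$selected]
  universe <- rownames(es$values)
  enrichment <- enrich(responders, universe, gene_sets,
                       score_threshold = score_threshold,
                       min_set_size = min_set_size,
                       max_set_size = max_set_size,
                       use_adjusted = use_adjusted)
  map <- build_enrichment_map(enrichment, gene_sets, universe,
                              edge_threshold = edge_threshold)
  structure(list(expression = es, profiles = profiles, clusters = clusters,
                 differential = differential, responders = responders,
                 enrichment = enrichment, map = map),
            class = "training_map_analysis")
}

#' @export
print.training_map_analysis <- function(x, ...) {
  cat("<training_map_analysis>\n")
  cat(sprintf("  %d genes, %d clusters, %d responders selected\n",
              nrow(x$differential), x$clusters$k, length(x$responders)))
  cat(sprintf("  %d/%d gene sets significant; map: %d node(s), %d edge(s), %d component(s)\n",
              sum(x$enrichment$significant), nrow(x$enrichment),
              nrow(x$map$nodes), nrow(x$map$edges),
              length(unique(x$map$nodes$component))))
  invisible(x)
}
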