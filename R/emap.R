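#' Set-overlap coefficients
#'
#' `jaccard()` is the intersection over the union; `overlap_coef()` is the
#' intersection over the smaller set; `overlap_score()` is their average and
#' serves as the edge weight of the enrichment map. All three lie in
#' \[0, 1\], are symmetric, and satisfy jaccard <= overlap_score <=
#' overlap coefficient.
#'
#' @param a,b Non-empty character vectors of gene ids (treated as sets).
#' @return A single number in \[0, 1\].
#' @export
#'
#' @examples
#' jaccard(c("A", "B"), c("B", "C"))        # 1/3
#' overlap_coef(c("A", "B"), c("B", "C"))   # 1/2
#' overlap_score(c("A", "B"), c("B", "C"))  # 5/12
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) abort("Sets must be non-empty.")
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' @rdname jaccard
#' @export
overlap_coef <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) abort("Sets must be non-empty.")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' @rdname jaccard
#' @export
overlap_score <- function(a, b) {
  (jaccard(a, b) + overlap_coef(a, b)) / 2
}

#' Build a functional enrichment map
#'
#' Nodes are the significant gene sets from an [enrich()] result; each node
#' carries its source tag, its size (member count after universe
#' intersection — the same count the enrichment statistic used) and its
#' enrichment score. Every pair of nodes whose universe-intersected
#' memberships reach `edge_threshold` on the overlap score (the average of
#' the Jaccard and overlap coefficients) is joined by an edge, and
#' components of the resulting similarity graph are labelled with
#' [tarjan_components()].
#'
#' @param results Tibble from [enrich()] computed on this collection and
#'   universe.
#' @param gene_sets The gene-set tibble the enrichment was run against.
#' @param universe Character vector of all gene ids under consideration.
#' @param edge_threshold Minimum overlap score for an edge, in \[0, 1\].
#' @return An object of class `enrichment_map`: list with `nodes` (tibble
#'   `set`, `source`, `size`, `score`, `component`), `edges` (tibble
#'   `set_a`, `set_b`, `jaccard`, `overlap_coef`, `overlap_score`, with
#'   `set_a` lexicographically first) and `edge_threshold`.
#' @export
build_enrichment_map <- function(results, gene_sets, universe,
                                 edge_threshold = 0.25) {
  stopifnot(is.data.frame(results),
            all(c("set", "source", "K", "p", "score", "significant") %in% names(results)))
  universe <- unique(toupper(universe))
  sig <- results[results$significant, ]
  missing_sets <- setdiff(sig$set, gene_sets$set)
  if (length(missing_sets) > 0) {
    abort(paste0("Result set(s) absent from the collection: ",
                 paste(missing_sets, collapse = ", ")))
  }
  nodes <- tibble(set = sig$set, source = sig$source,
                  size = sig$K, score = sig$score)
  members <- purrr::map(
    gene_sets$members[match(sig$set, gene_sets$set)],
    ~ intersect(.x, universe)
  )
  names(members) <- sig$set

  edges <- tibble(set_a = character(0), set_b = character(0),
                  jaccard = numeric(0), overlap_coef = numeric(0),
                  overlap_score = numeric(0))
  if (nrow(nodes) >= 2) {
    pairs <- utils::combn(nodes$set, 2)
    rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      jc <- jaccard(members[[a]], members[[b]])
      oc <- overlap_coef(members[[a]], members[[b]])
      os <- (jc + oc) / 2
      if (os >= edge_threshold) {
        ord <- sort(c(a, b), method = "radix")
        tibble(set_a = ord[1], set_b = ord[2],
               jaccard = jc, overlap_coef = oc, overlap_score = os)
      }
    })
    rows <- purrr::compact(rows)
    if (length(rows) > 0) edges <- dplyr::bind_rows(rows)
  }

  comp <- tarjan_components(nodes$set, edges[, c("set_a", "set_b")])
  nodes$component <- comp$component[match(nodes$set, comp$node)]
  structure(list(nodes = nodes, edges = edges,
                 edge_threshold = edge_threshold),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("<enrichment_map> %d node(s), %d edge(s), %d component(s) (edge threshold %s)\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$component)), format(x$edge_threshold)))
  if (nrow(x$nodes) > 0) print(x$nodes, n = 10)
  invisible(x)
}

#' Convert an enrichment map to an igraph object
#'
#' @param map An `enrichment_map`.
#' @return An undirected `igraph` graph carrying all node and edge
#'   attributes.
#' @export
as_igraph <- function(map) {
  stopifnot(inherits(map, "enrichment_map"))
  nodes <- map$nodes[order_c(map$nodes$set), ]
  edges <- map$edges[order_c(map$edges$set_a, map$edges$set_b), ]
  if (nrow(nodes) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
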