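#' Read an expression matrix and its sample-annotation sidecar
#'
#' The matrix file is tab-separated with gene ids in the first column and a
#' header row of sample ids; the annotation file is tab-separated with
#' columns `sample_id`, `stimulus`, `state`, `replicate`. Gene ids are
#' upper-cased at ingest so that downstream comparisons with GMT collections
#' are case-insensitive.
#'
#' @param matrix_path Path to the tab-separated expression matrix.
#' @param annotation_path Path to the tab-separated annotation table.
#'
#' @return An [expression_set()]; sample order follows the matrix header.
#' @export
read_expression <- function(matrix_path, annotation_path) {
  raw <- readr::read_tsv(matrix_path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("Expression matrix needs a gene column and >=1 sample column.")
  gene_ids <- toupper(raw[[1]])
  sample_ids <- names(raw)[-1]
  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, sample_ids))
  bad <- which(is.na(num) & !is.na(as.matrix(raw[-1])), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-numeric cell '%s' at gene '%s', sample '%s'.",
                  as.matrix(raw[-1])[bad[1, , drop = FALSE]],
                  gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing value at gene '%s', sample '%s'.",
                  gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  rownames(num) <- gene_ids
  ann <- readr::read_tsv(annotation_path,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           stimulus = readr::col_character(),
                           state = readr::col_character(),
                           replicate = readr::col_integer()
                         ),
                         progress = FALSE)
  expression_set(num, ann)
}

#' Write an expression set as matrix + annotation TSV files
#'
#' Inverse of [read_expression()]; rewriting the same object produces
#' byte-identical files.
#'
#' @param es An [expression_set()].
#' @param matrix_path,annotation_path Output paths.
#' @return `es`, invisibly.
#' @export
write_expression <- function(es, matrix_path, annotation_path) {
  tab <- as_tibble(es$values, rownames = "gene")
  readr::write_tsv(tab, matrix_path, progress = FALSE)
  readr::write_tsv(es$annotations, annotation_path, progress = FALSE)
  invisible(es)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated
#' (the Broad dialect). Members are upper-cased and deduplicated. Because the
#' pipeline merges several collections (KEGG, GO, Panther, Reactome) into one
#' map, each set name is disambiguated as `"name|tag"` using the collection's
#' source tag.
#'
#' @param path Path to a GMT file.
#' @param source_tag Single letter identifying the collection:
#'   `"K"` (KEGG), `"G"` (Gene Ontology), `"P"` (Panther), `"R"` (Reactome).
#'
#' @return A tibble with one row per set and columns `set` (disambiguated
#'   `"name|tag"`), `name`, `source`, `description`, and `members`
#'   (a list column of upper-cased, deduplicated gene ids). Sets left empty
#'   after cleanup are dropped with a warning.
#' @export
read_gmt <- function(path, source_tag) {
  source_tag <- match.arg(source_tag, c("K", "G", "P", "R"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has %d field(s); at least 3 required (%s).",
                  short[1], lengths(fields)[short[1]], path))
  }
  rows <- purrr::map(fields, function(f) {
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    tibble(name = f[1], description = f[2], members = list(members))
  })
  out <- dplyr::bind_rows(rows)
  empty <- lengths(out$members) == 0
  if (any(empty)) {
    warn(paste0("Dropping empty gene set(s): ",
                paste(out$name[empty], collapse = ", ")))
    out <- out[!empty, ]
  }
  out$source <- source_tag
  out$set <- paste0(out$name, "|", source_tag)
  out[, c("set", "name", "source", "description", "members")]
}

#' Write a gene-set collection to GMT
#'
#' @param sets Gene-set tibble as returned by [read_gmt()] (columns `name`,
#'   `description`, `members`).
#' @param path Output path.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$name, sets$description, sets$members),
    function(name, desc, members) paste(c(name, desc, members), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(sets)
}

#' Export an enrichment map as node/edge tables and GraphML
#'
#' Node rows carry `set`, `source`, `size`, `score`, `component`; edge rows
#' carry `set_a`, `set_b`, `jaccard`, `overlap_coef`, `overlap_score` with
#' `set_a` lexicographically before `set_b`. Rows are sorted (C locale) so
#' repeated writes of the same map are byte-identical.
#'
#' @param map An `enrichment_map` from [build_enrichment_map()].
#' @param node_path,edge_path Output TSV paths.
#' @param graphml_path Optional GraphML output path carrying the same
#'   attributes, for external viewers (Cytoscape, Gephi).
#' @return `map`, invisibly.
#' @export
write_enrichment_map <- function(map, node_path, edge_path, graphml_path = NULL) {
  stopifnot(inherits(map, "enrichment_map"))
  nodes <- map$nodes[order_c(map$nodes$set), ]
  edges <- map$edges
  flip <- edges$set_a > edges$set_b
  if (any(flip)) {
    tmp <- edges$set_a[flip]
    edges$set_a[flip] <- edges$set_b[flip]
    edges$set_b[flip] <- tmp
  }
  edges <- edges[order_c(edges$set_a, edges$set_b), ]
  readr::write_tsv(nodes, node_path, progress = FALSE)
  readr::write_tsv(edges, edge_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    g <- as_igraph(map)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(map)
}

#' Read back node/edge tables written by [write_enrichment_map()]
#'
#' @param node_path,edge_path Paths written by [write_enrichment_map()].
#' @return An `enrichment_map` (without re-deriving components; the stored
#'   `component` column is kept).
#' @export
read_enrichment_map <- function(node_path, edge_path) {
  nodes <- readr::read_tsv(node_path, col_types = "ccidi", progress = FALSE)
  edges <- readr::read_tsv(edge_path, col_types = "ccddd", progress = FALSE)
  structure(list(nodes = nodes, edges = edges, edge_threshold = NA_real_),
            class = "enrichment_map")
}

# C-locale (radix) ordering: stable across platforms and locales.
order_c <- function(...) order(..., method = "radix")
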