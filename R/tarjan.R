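#' Strongly connected components via Tarjan's algorithm
#'
#' Labels the strongly connected components of the directed graph obtained
#' by replacing every undirected edge with two opposed arcs (on such a
#' symmetrized similarity graph the SCCs coincide with the connected
#' components). The single-pass low-link algorithm is implemented
#' iteratively with an explicit frame stack, so deep graphs cannot hit a
#' recursion limit. Component ids are renumbered 1..C by the
#' lexicographically smallest node they contain, making the labeling
#' deterministic.
#'
#' @param nodes Character vector of node names.
#' @param edges Data frame whose first two columns name the endpoints of
#'   each undirected edge; self-loops are rejected.
#' @return A tibble with columns `node` and `component`.
#' @export
#'
#' @examples
#' tarjan_components(c("a", "b", "c", "d"),
#'                   data.frame(from = c("a", "b"), to = c("b", "c")))
tarjan_components <- function(nodes, edges) {
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes))
  n <- length(nodes)
  if (n == 0) return(tibble(node = character(0), component = integer(0)))
  from <- match(as.character(edges[[1]]), nodes)
  to <- match(as.character(edges[[2]]), nodes)
  if (anyNA(from) || anyNA(to)) abort("Edge endpoint not in `nodes`.")
  if (any(from == to)) {
    abort(sprintf("Self-loop on node '%s'.", nodes[from[from == to][1]]))
  }
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (e in seq_along(from)) {
    adj[[from[e]]] <- c(adj[[from[e]]], to[e])
    adj[[to[e]]] <- c(adj[[to[e]]], from[e])
  }

  index <- rep(NA_integer_, n)
  lowlink <- integer(n)
  on_stack <- logical(n)
  comp <- rep(NA_integer_, n)
  counter <- 0L
  n_comp <- 0L
  tarjan_stack <- integer(0)

  for (root in seq_len(n)) {
    if (!is.na(index[root])) next
    # explicit DFS frames: node and position in its adjacency list
    frame_node <- integer(0)
    frame_pos <- integer(0)

    push <- function(v) {
      counter <<- counter + 1L
      index[v] <<- counter
      lowlink[v] <<- counter
      tarjan_stack <<- c(tarjan_stack, v)
      on_stack[v] <<- TRUE
      frame_node <<- c(frame_node, v)
      frame_pos <<- c(frame_pos, 0L)
    }
    push(root)
    while (length(frame_node) > 0) {
      top <- length(frame_node)
      v <- frame_node[top]
      pos <- frame_pos[top] + 1L
      if (pos <= length(adj[[v]])) {
        frame_pos[top] <- pos
        w <- adj[[v]][pos]
        if (is.na(index[w])) {
          push(w)
        } else if (on_stack[w]) {
          lowlink[v] <- min(lowlink[v], index[w])
        }
      } else {
        # v is finished: maybe close a component, then propagate lowlink up
        if (lowlink[v] == index[v]) {
          n_comp <- n_comp + 1L
          repeat {
            w <- tarjan_stack[length(tarjan_stack)]
            tarjan_stack <- tarjan_stack[-length(tarjan_stack)]
            on_stack[w] <- FALSE
            comp[w] <- n_comp
            if (w == v) break
          }
        }
        frame_node <- frame_node[-top]
        frame_pos <- frame_pos[-top]
        if (top > 1) {
          parent <- frame_node[top - 1L]
          lowlink[parent] <- min(lowlink[parent], lowlink[v])
        }
      }
    }
  }

  # deterministic relabeling by smallest member node name
  firsts <- vapply(seq_len(n_comp),
                   function(cid) sort(nodes[comp == cid], method = "radix")[1],
                   character(1))
  relabel <- match(firsts, sort(firsts, method = "radix"))
  tibble(node = nodes, component = relabel[comp])
}
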