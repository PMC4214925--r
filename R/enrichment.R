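#' Hypergeometric upper-tail enrichment probability
#'
#' P(X >= k) for X ~ hypergeometric with `N` genes in the universe, `K` of
#' them in the set, and `n` drawn (the responder list). This is the one-sided
#' Fisher exact p-value for over-representation. Vectorized over all
#' arguments.
#'
#' @param N Universe size.
#' @param K Set size within the universe.
#' @param n Responder-list size.
#' @param k Hits (responders in the set).
#' @return Upper-tail probability in \[0, 1\].
#' @export
#'
#' @examples
#' hypergeom_p(20, 5, 5, 5)  # 1 / choose(20, 5)
hypergeom_p <- function(N, K, n, k) {
  bad <- k < 0 | k > pmin(K, n) | K > N | n > N | K < 0 | n < 0 | N < 0
  if (any(bad)) {
    abort(sprintf("Invalid hypergeometric arguments: N=%s K=%s n=%s k=%s.",
                  N[bad][1], K[bad][1], n[bad][1], k[bad][1]))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set enrichment of a responder list
#'
#' Tests each gene set for over-representation of responder genes with the
#' one-sided hypergeometric test, after intersecting every set with the
#' universe (all genes on the normalized array). Sets whose intersected size
#' falls outside `[min_set_size, max_set_size]` are excluded. p-values are
#' BH-adjusted across all tested sets as one family (the merged K/G/P/R
#' collections). The enrichment score is -log10(p); a set is significant
#' when its score exceeds `score_threshold` (the default 1.3 corresponds to
#' p < 0.05). With `use_adjusted = TRUE` the significance gate is applied to
#' -log10 of the adjusted p-value instead, while `score` always reports the
#' raw-p score.
#'
#' @param responders Character vector of responder gene ids; must be a
#'   subset of `universe`.
#' @param universe Character vector of all gene ids under consideration.
#' @param gene_sets Gene-set tibble ([read_gmt()] layout: columns `set`,
#'   `source`, `members`).
#' @param score_threshold Significance threshold on the enrichment score.
#' @param min_set_size,max_set_size Set-size window (after universe
#'   intersection) outside which sets are excluded from testing.
#' @param use_adjusted Gate significance on the BH-adjusted p-value.
#' @return A tibble with one row per tested set: `set`, `source`, `N`, `K`,
#'   `n`, `k`, `p`, `p_adjusted`, `score`, `significant`.
#' @export
enrich <- function(responders, universe, gene_sets,
                   score_threshold = 1.3,
                   min_set_size = 5, max_set_size = 500,
                   use_adjusted = FALSE) {
  stopifnot(is.data.frame(gene_sets),
            all(c("set", "source", "members") %in% names(gene_sets)))
  universe <- unique(toupper(universe))
  responders <- unique(toupper(responders))
  stray <- setdiff(responders, universe)
  if (length(stray) > 0) {
    abort(paste0("Responder gene(s) not in universe: ",
                 paste(utils::head(stray, 5), collapse = ", ")))
  }
  N <- length(universe)
  n <- length(responders)
  members_u <- purrr::map(gene_sets$members, ~ intersect(.x, universe))
  K <- lengths(members_u)
  keep <- K >= min_set_size & K <= max_set_size
  if (any(!keep)) {
    inform(sprintf("Excluding %d set(s) outside the size window [%d, %d] after universe intersection.",
                   sum(!keep), min_set_size, max_set_size))
  }
  out <- tibble(set = gene_sets$set[keep],
                source = gene_sets$source[keep],
                N = N,
                K = unname(K[keep]),
                n = n,
                k = unname(vapply(members_u[keep],
                                  function(m) length(intersect(m, responders)),
                                  integer(1))))
  out$p <- hypergeom_p(out$N, out$K, out$n, out$k)
  out$p_adjusted <- bh_adjust(out$p)
  out$score <- -log10(out$p)
  gate <- if (use_adjusted) -log10(out$p_adjusted) else out$score
  out$significant <- gate > score_threshold
  out
}
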