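# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# A balanced 2x2 expression set with `reps` replicates per cell.
# `effects` is an optional function(stimulus, state) returning the mean shift
# added to `baseline_mean` for given cells (applied to the genes in
# `shifted_genes`).
make_es <- function(n_genes = 10, reps = 3, noise_sd = 0, seed = 1,
                    baseline_mean = 8, effects = NULL, shifted_genes = NULL) {
  ann <- expand.grid(replicate = seq_len(reps),
                     state = c("baseline", "stimulated"),
                     stimulus = c("trainer", "comparator"),
                     stringsAsFactors = FALSE)
  ann$sample_id <- sprintf("%s_%s_r%d", ann$stimulus, ann$state, ann$replicate)
  genes <- sprintf("G%03d", seq_len(n_genes))
  withr::with_seed(seed, {
    m <- matrix(baseline_mean + rnorm(n_genes * nrow(ann), 0, noise_sd),
                n_genes, nrow(ann), dimnames = list(genes, ann$sample_id))
  })
  if (!is.null(effects)) {
    rows <- if (is.null(shifted_genes)) seq_len(n_genes) else match(shifted_genes, genes)
    for (j in seq_len(nrow(ann))) {
      m[rows, j] <- m[rows, j] + effects(ann$stimulus[j], ann$state[j])
    }
  }
  expression_set(m, ann[, c("sample_id", "stimulus", "state", "replicate")])
}

# Gene-set tibble in read_gmt() layout built from a named list of members.
make_sets <- function(members, source = "K") {
  src <- rep_len(source, length(members))
  tibble::tibble(
    set = paste0(names(members), "|", src),
    name = names(members),
    source = src,
    description = "fixture",
    members = lapply(members, toupper)
  )
}

# Write a small matrix + annotation TSV pair; returns the two paths.
write_expr_fixture <- function(lines_matrix, lines_ann, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "expr.tsv")
  ap <- file.path(dir, "ann.tsv")
  writeLines(lines_matrix, mp)
  writeLines(lines_ann, ap)
  list(matrix = mp, annotation = ap)
}

# Brute-force BH oracle: explicit min-over-suffix on the sorted vector.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(sp[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive hypergeometric upper-tail oracle by enumerating all C(N, n)
# draws from a universe whose first K elements are hits.
hyper_oracle <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subs <- utils::combn(N, n)
  hits <- colSums(subs <= K)
  mean(hits >= k)
}

# Connected components by brute-force transitive closure (Warshall).
reach_components <- function(nodes, edges) {
  n <- length(nodes)
  reach <- diag(TRUE, n)
  if (nrow(edges) > 0) {
    a <- match(edges[[1]], nodes)
    b <- match(edges[[2]], nodes)
    reach[cbind(a, b)] <- TRUE
    reach[cbind(b, a)] <- TRUE
  }
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# Canonical form of a partition: sorted list of sorted member groups,
# independent of label identity.
partition_canonical <- function(ids, labels) {
  groups <- split(sort(ids), labels[order(ids)])
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}
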