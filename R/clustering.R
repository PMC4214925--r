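#' Cluster gene response profiles with k-means
#'
#' Partitions genes by their response profiles using Lloyd's algorithm with
#' k-means++ seeding, keeping the best of `restarts` runs by within-cluster
#' sum of squares (WCSS). Numeric profile columns are standardized to zero
#' mean and unit standard deviation before clustering so no dimension
#' dominates by scale. If a Lloyd iteration empties a cluster, the point
#' farthest from its current centroid is split off to repopulate it, so the
#' returned solution never contains an empty cluster. The run is
#' deterministic given `seed`.
#'
#' @param profiles Data frame with a `gene` column and numeric profile
#'   columns, e.g. from [response_profiles()].
#' @param k Number of clusters; must not exceed the number of distinct
#'   profiles.
#' @param seed Integer seed for the k-means++ draws.
#' @param restarts Number of independent seeded runs; the best by WCSS wins.
#' @param max_iter Lloyd iteration cap per run.
#'
#' @return An object of class `profile_clusters`: list with `assignment`
#'   (tibble `gene`, `cluster` with labels 1..k), `centers` (k x d matrix in
#'   standardized profile space), `wcss`, `k`, `seed`, `restarts`,
#'   `n_iter_run` (iterations of the winning run), and `data` (the
#'   standardized profile matrix, for plotting).
#' @export
#'
#' @examples
#' set.seed(1)
#' profs <- tibble::tibble(gene = paste0("g", 1:40),
#'                         a = c(rnorm(20, -3), rnorm(20, 3)),
#'                         b = c(rnorm(20, -3), rnorm(20, 3)))
#' cl <- cluster_profiles(profs, k = 2)
#' glance(cl)
cluster_profiles <- function(profiles, k, seed = 17, restarts = 10,
                             max_iter = 100) {
  stopifnot(is.data.frame(profiles), "gene" %in% names(profiles),
            k >= 1, restarts >= 1)
  num_cols <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "gene")
  if (length(num_cols) == 0) abort("`profiles` has no numeric profile columns.")
  x <- as.matrix(profiles[num_cols])
  rownames(x) <- profiles$gene
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0  # constant dimensions carry no signal
  x <- x[, , drop = FALSE]
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    abort(sprintf("k = %d exceeds the %d distinct profiles.", k, n_distinct))
  }

  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      run <- lloyd_run(x, k, max_iter)
      if (is.null(best) || run$wcss < best$wcss) best <- run
    }
  })

  structure(list(
    assignment = tibble(gene = profiles$gene, cluster = best$cluster),
    centers = best$centers,
    wcss = best$wcss,
    k = k,
    seed = seed,
    restarts = restarts,
    n_iter_run = best$n_iter,
    data = x
  ), class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("<profile_clusters> %d genes in %d clusters (WCSS %.4g, %d restart(s))\n",
              nrow(x$assignment), x$k, x$wcss, x$restarts))
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

# Squared Euclidean distances from each row of x to each row of centers.
dist_sq <- function(x, centers) {
  d <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * tcrossprod(x, centers)
  pmax(d, 0)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- dist_sq(x, x[idx[1], , drop = FALSE])[, 1]
    for (i in 2:k) {
      if (all(d2 == 0)) {
        idx[i] <- sample.int(n, 1)
      } else {
        idx[i] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, dist_sq(x, x[idx[i], , drop = FALSE])[, 1])
    }
  }
  x[idx, , drop = FALSE]
}

lloyd_run <- function(x, k, max_iter) {
  centers <- kmeanspp_init(x, k)
  assign_old <- rep(0L, nrow(x))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist_sq(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # repair empty clusters: split off the point farthest from its centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(assign_new))
      if (length(empty) == 0) break
      cur <- d2[cbind(seq_len(nrow(x)), assign_new)]
      far <- which.max(cur)
      centers[empty[1], ] <- x[far, ]
      d2[, empty[1]] <- dist_sq(x, centers[empty[1], , drop = FALSE])[, 1]
      assign_new[far] <- empty[1]
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
    }
    if (identical(assign_new, assign_old) || iter >= max_iter) break
    assign_old <- assign_new
  }
  d2 <- dist_sq(x, centers)
  wcss <- sum(d2[cbind(seq_len(nrow(x)), assign_new)])
  list(cluster = assign_new, centers = centers, wcss = wcss, n_iter = iter)
}
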