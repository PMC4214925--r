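# Per-gene two-factor interaction testing and responder selection.
#
# The model for a single gene is the 2x2 fixed-effects OLS
#   value = mu + a.[stimulated] + b.[trainer] + c.[stimulated x trainer] + e
# so the comparator response is a, the trainer response is a + c, and the
# interaction c is exactly the difference between the responses the two
# stimuli elicit. Significance of c is the partial F-test of the full model
# against the additive one, with n - 4 residual degrees of freedom. All
# genes share the sample design, so one QR decomposition per design serves
# the whole matrix.

design_matrices <- function(annotations) {
  stim <- as.integer(annotations$state == "stimulated")
  train <- as.integer(annotations$stimulus == "trainer")
  x1 <- cbind(intercept = 1, stimulated = stim, trainer = train,
              interaction = stim * train)
  x0 <- x1[, 1:3, drop = FALSE]
  for (s in c("trainer", "comparator")) {
    for (st in c("baseline", "stimulated")) {
      n_cell <- sum(annotations$stimulus == s & annotations$state == st)
      if (n_cell == 0) abort(sprintf("Empty design cell (%s, %s).", s, st))
      if (n_cell < 2) {
        abort(sprintf("Group (%s, %s) has %d replicate(s); at least 2 required.",
                      s, st, n_cell))
      }
    }
  }
  list(full = x1, additive = x0)
}

# Vectorized fit; y is samples x genes.
fit_factorial <- function(y, annotations) {
  dm <- design_matrices(annotations)
  n <- nrow(y)
  df_res <- n - 4L
  qr1 <- qr(dm$full)
  qr0 <- qr(dm$additive)
  coefs <- qr.coef(qr1, y)
  rss1 <- colSums(qr.resid(qr1, y)^2)
  rss0 <- colSums(qr.resid(qr0, y)^2)
  c_hat <- coefs["interaction", ]
  a_hat <- coefs["stimulated", ]
  f_stat <- (rss0 - rss1) / (rss1 / df_res)
  p <- pf(f_stat, 1, df_res, lower.tail = FALSE)
  # zero residual variance: the F-statistic is undefined; report certainty
  scale <- pmax(colSums(y^2), 1)
  degen <- rss1 <= scale * 1e-20
  if (any(degen)) {
    warn(sprintf("%d gene(s) with zero residual variance; p set to 0 (interaction != 0) or 1 (interaction == 0).",
                 sum(degen)))
    p[degen] <- ifelse(abs(c_hat[degen]) > 1e-8, 0, 1)
    f_stat[degen] <- ifelse(abs(c_hat[degen]) > 1e-8, Inf, 0)
  }
  tibble(gene = colnames(y),
         beta_trainer = unname(a_hat + c_hat),
         beta_comparator = unname(a_hat),
         interaction_estimate = unname(c_hat),
         statistic = unname(f_stat),
         p_interaction = unname(p))
}

#' Factorial interaction test for a single gene
#'
#' Fits the two-factor OLS model described in [differential_test()] to one
#' gene's annotated values and tests the stimulus-by-state interaction with
#' a partial F-test against the additive model.
#'
#' @param data Data frame with columns `value`, `stimulus`
#'   (`"trainer"`/`"comparator"`) and `state` (`"baseline"`/`"stimulated"`);
#'   all four cells must hold at least 2 replicates.
#' @return One-row tibble: `beta_trainer`, `beta_comparator`,
#'   `interaction_estimate` (their difference), `statistic` (F on 1 and
#'   n - 4 df) and `p_interaction`.
#' @export
#'
#' @examples
#' d <- tidyr::expand_grid(stimulus = c("trainer", "comparator"),
#'                         state = c("baseline", "stimulated"), rep = 1:3)
#' d$value <- 8 + 2 * (d$stimulus == "trainer" & d$state == "stimulated")
#' factorial_test(d)
factorial_test <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("value", "stimulus", "state") %in% names(data)))
  y <- matrix(data$value, ncol = 1, dimnames = list(NULL, "gene"))
  fit <- fit_factorial(y, data)
  fit$gene <- NULL
  fit
}

#' Per-gene factorial tests across an expression set
#'
#' Runs the two-factor interaction test on every gene, attaches cluster
#' labels, applies the Benjamini-Hochberg adjustment (within each cluster by
#' default, so each k-means cluster is its own testing family), and flags
#' responders: genes whose adjusted interaction p-value clears `alpha` and
#' whose trainer response exceeds the comparator response.
#'
#' @param es An [expression_set()]; a balanced or unbalanced 2x2 design with
#'   at least 2 replicates per cell.
#' @param clusters Optional [cluster_profiles()] result or a data frame with
#'   columns `gene`, `cluster`. Absent, all genes form a single family.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param per_cluster Adjust within each cluster (default) or globally.
#' @return A tibble with one row per gene: `gene`, `cluster`,
#'   `beta_trainer`, `beta_comparator`, `interaction_estimate`, `statistic`,
#'   `p_interaction`, `p_adjusted`, `selected`.
#' @export
differential_test <- function(es, clusters = NULL, alpha = 0.05,
                              per_cluster = TRUE) {
  stopifnot(inherits(es, "expression_set"))
  fit <- fit_factorial(t(es$values), es$annotations)
  if (inherits(clusters, "profile_clusters")) clusters <- clusters$assignment
  if (is.null(clusters)) {
    fit$cluster <- 1L
  } else {
    stopifnot(all(c("gene", "cluster") %in% names(clusters)))
    fit <- dplyr::left_join(fit, clusters[, c("gene", "cluster")], by = "gene")
    if (anyNA(fit$cluster)) {
      abort(paste0("Gene(s) without a cluster label: ",
                   paste(utils::head(fit$gene[is.na(fit$cluster)], 5), collapse = ", ")))
    }
  }
  fam <- if (per_cluster) fit$cluster else rep(1L, nrow(fit))
  fit$p_adjusted <- unsplit(lapply(split(fit$p_interaction, fam), bh_adjust), fam)
  fit$selected <- fit$p_adjusted < alpha & fit$interaction_estimate > 0
  fit[, c("gene", "cluster", "beta_trainer", "beta_comparator",
          "interaction_estimate", "statistic", "p_interaction",
          "p_adjusted", "selected")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes the adjusted values q(i) = min over j >= i of p(j) * m / j on the
#' sorted vector, capped at 1, and maps them back to input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
#'
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / (m:1)))
  q[order(o)]
}

#' Select responder genes
#'
#' Recomputes the BH adjustment on the chosen family (per cluster or global)
#' and returns the genes with adjusted p below `alpha` whose trainer response
#' exceeds their comparator response (positive interaction estimate) — the
#' genes with a significantly weaker comparator response relative to the
#' trainer response.
#'
#' @param results Tibble from [differential_test()].
#' @param alpha Significance threshold on the adjusted p-value.
#' @param per_cluster Adjust within each cluster (default) or globally.
#' @return Character vector of responder gene ids, in input order.
#' @export
select_responders <- function(results, alpha = 0.05, per_cluster = TRUE) {
  stopifnot(is.data.frame(results),
            all(c("gene", "p_interaction", "interaction_estimate") %in% names(results)))
  fam <- if (per_cluster && "cluster" %in% names(results)) results$cluster else rep(1L, nrow(results))
  q <- unsplit(lapply(split(results$p_interaction, fam), bh_adjust), fam)
  results$gene[q < alpha & results$interaction_estimate > 0]
}
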