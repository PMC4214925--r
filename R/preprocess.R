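#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto one common value distribution: the
#' reference distribution is the vector of row-wise means of the rank-sorted
#' columns, and each value is replaced by the reference value at its rank.
#' Ties within a column receive the mean of the reference values their rank
#' run spans, so the result does not depend on input order. The operation is
#' idempotent (exactly so on tie-free data).
#'
#' @param es An [expression_set()] with at least one gene and one sample.
#' @return An [expression_set()] with normalized values and unchanged
#'   annotations.
#' @export
#'
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ann <- data.frame(sample_id = c("s1", "s2"),
#'                   stimulus = "trainer",
#'                   state = c("baseline", "stimulated"), replicate = 1L)
#' quantile_normalize(expression_set(m, ann))$values
quantile_normalize <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  x <- es$values
  sorted <- apply(x, 2, sort)
  if (nrow(x) == 1) sorted <- matrix(sorted, nrow = 1)
  ref <- rowMeans(sorted)
  cum0 <- c(0, cumsum(ref))
  out <- x
  for (j in seq_len(ncol(x))) {
    rmin <- rank(x[, j], ties.method = "min")
    rmax <- rank(x[, j], ties.method = "max")
    out[, j] <- (cum0[rmax + 1L] - cum0[rmin]) / (rmax - rmin + 1L)
  }
  es$values <- out
  es
}

#' Per-gene stimulus response and signal-to-noise ratio
#'
#' The response of a gene to a stimulus is the difference of its group means,
#' stimulated minus baseline, in log2 units. The signal-to-noise ratio
#' standardizes that difference by the summed group standard deviations:
#' \deqn{snr = (\mu_{stim} - \mu_{base}) / (s_{stim} + s_{base})}
#' with sample standard deviations (n-1 denominator) and the denominator
#' floored at 1e-8 so zero-variance genes stay finite. With
#' `reference = "other_stimulus"` the contrast is instead taken between the
#' stimulated cells of the two arms (stimulus minus the other arm).
#'
#' @param es An [expression_set()].
#' @param stimulus `"trainer"` or `"comparator"`.
#' @param reference `"baseline"` (default: stimulated vs baseline within the
#'   arm) or `"other_stimulus"` (stimulated vs the other arm's stimulated).
#' @return A tibble with columns `gene`, `response` (log2 units) and `snr`
#'   (unitless). Each contrasted group must hold at least 2 replicates.
#' @export
signal_to_noise <- function(es, stimulus = c("trainer", "comparator"),
                            reference = c("baseline", "other_stimulus")) {
  stopifnot(inherits(es, "expression_set"))
  stimulus <- match.arg(stimulus)
  reference <- match.arg(reference)
  hi <- cell_columns(es, stimulus, "stimulated", min_rep = 2)
  lo <- if (reference == "baseline") {
    cell_columns(es, stimulus, "baseline", min_rep = 2)
  } else {
    other <- setdiff(c("trainer", "comparator"), stimulus)
    cell_columns(es, other, "stimulated", min_rep = 2)
  }
  x_hi <- es$values[, hi, drop = FALSE]
  x_lo <- es$values[, lo, drop = FALSE]
  m_hi <- rowMeans(x_hi)
  m_lo <- rowMeans(x_lo)
  s_hi <- row_sds(x_hi)
  s_lo <- row_sds(x_lo)
  tibble(gene = rownames(es$values),
         response = unname(m_hi - m_lo),
         snr = unname((m_hi - m_lo) / pmax(s_hi + s_lo, 1e-8)))
}

#' Per-gene response profiles for clustering
#'
#' Assembles the four-dimensional profile used to cluster genes: the
#' signal-to-noise ratio and the raw mean response of each gene under each
#' stimulus (stimulated vs baseline). This captures both the magnitude and
#' the reliability of the response in each arm.
#'
#' @param es An [expression_set()] with >=2 replicates in all four cells.
#' @return A tibble with columns `gene`, `snr_trainer`, `snr_comparator`,
#'   `response_trainer`, `response_comparator`.
#' @export
response_profiles <- function(es) {
  tr <- signal_to_noise(es, "trainer")
  co <- signal_to_noise(es, "comparator")
  tibble(gene = tr$gene,
         snr_trainer = tr$snr,
         snr_comparator = co$snr,
         response_trainer = tr$response,
         response_comparator = co$response)
}

row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}
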