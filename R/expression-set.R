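#' Expression set: a gene x sample matrix with factorial sample annotations
#'
#' Container for log2 expression values of genes (rows) across samples
#' (columns), where each sample is annotated with a stimulus arm
#' (`"trainer"` or `"comparator"`), a treatment state (`"baseline"` or
#' `"stimulated"`) and a replicate number. This is the unit every pipeline
#' stage consumes.
#'
#' @param values Numeric matrix, genes as rows, with unique rownames
#'   (gene ids) and colnames (sample ids). All values must be finite.
#' @param annotations Data frame with columns `sample_id`, `stimulus`,
#'   `state`, `replicate` covering every column of `values`.
#'
#' @return An object of class `expression_set`: a list with elements
#'   `values` (the matrix, gene ids upper-cased) and `annotations`
#'   (a tibble ordered to match the matrix columns).
#' @export
#'
#' @examples
#' m <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("TNF", "IL6"), paste0("s", 1:4)))
#' ann <- data.frame(sample_id = paste0("s", 1:4),
#'                   stimulus = rep(c("trainer", "comparator"), each = 2),
#'                   state = rep(c("baseline", "stimulated"), 2),
#'                   replicate = 1L)
#' es <- expression_set(m, ann)
#' es
expression_set <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  rownames(values) <- toupper(rownames(values))
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0) {
    abort(paste0("Duplicate gene id(s): ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicate sample id(s): ", paste(dup_s, collapse = ", ")))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite value at gene '%s', sample '%s'.",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  annotations <- as_tibble(annotations)
  needed <- c("sample_id", "stimulus", "state", "replicate")
  missing_cols <- setdiff(needed, names(annotations))
  if (length(missing_cols) > 0) {
    abort(paste0("Annotation columns missing: ", paste(missing_cols, collapse = ", ")))
  }
  missing_samples <- setdiff(colnames(values), annotations$sample_id)
  if (length(missing_samples) > 0) {
    abort(paste0("Sample(s) in matrix missing from annotations: ",
                 paste(missing_samples, collapse = ", ")))
  }
  annotations <- annotations[match(colnames(values), annotations$sample_id), needed]
  bad_stim <- setdiff(unique(annotations$stimulus), c("trainer", "comparator"))
  if (length(bad_stim) > 0) {
    abort(paste0("Unknown stimulus value(s): ", paste(bad_stim, collapse = ", "),
                 " (expected 'trainer' or 'comparator')."))
  }
  bad_state <- setdiff(unique(annotations$state), c("baseline", "stimulated"))
  if (length(bad_state) > 0) {
    abort(paste0("Unknown state value(s): ", paste(bad_state, collapse = ", "),
                 " (expected 'baseline' or 'stimulated')."))
  }
  rep_num <- suppressWarnings(as.integer(annotations$replicate))
  if (anyNA(rep_num) || any(rep_num < 1)) {
    abort("`replicate` must be a positive integer for every sample.")
  }
  annotations$replicate <- rep_num
  structure(list(values = values, annotations = annotations),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cells <- table(paste(x$annotations$stimulus, x$annotations$state, sep = "/"))
  cat(sprintf("<expression_set> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  samples per (stimulus/state) cell:\n")
  for (nm in names(cells)) cat(sprintf("    %-22s %d\n", nm, cells[[nm]]))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' @rdname expression_set
#' @param x An `expression_set`.
#' @param ... Unused.
#' @export
as_tibble.expression_set <- function(x, ...) {
  out <- as_tibble(x$values, rownames = "gene")
  out <- tidyr::pivot_longer(out, -"gene",
                             names_to = "sample_id", values_to = "value")
  dplyr::left_join(out, x$annotations, by = "sample_id")
}

# Column indices of one (stimulus, state) cell; errors if the cell is absent
# or (when min_rep = 2) under-replicated.
cell_columns <- function(es, stimulus, state, min_rep = 1) {
  idx <- which(es$annotations$stimulus == stimulus & es$annotations$state == state)
  if (length(idx) < min_rep) {
    abort(sprintf("Group (%s, %s) has %d replicate(s); at least %d required.",
                  stimulus, state, length(idx), min_rep))
  }
  idx
}
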