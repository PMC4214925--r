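#' Simulate a two-stimulus training experiment with planted ground truth
#'
#' Generates a gene x sample log2 expression matrix for a balanced 2x2
#' factorial design (stimulus: trainer vs comparator; state: baseline vs
#' stimulated), a gene-set collection containing planted and decoy sets, and
#' the ground truth behind both. A set of responder genes gains
#' `trainer_effect` log2 units in the (trainer, stimulated) cell and
#' `comparator_effect` in the (comparator, stimulated) cell — the
#' trainer-specific interaction every downstream stage is built to detect.
#' All other genes sit at the 8.0 log2-unit baseline, and every cell receives
#' i.i.d. Gaussian noise.
#'
#' Planted sets draw `round(planted_purity * planted_set_size)` members from
#' the responder genes, laid out as overlapping windows (stride = half a
#' window) over the sampled responder list so that consecutive planted sets
#' share about half their responder members, emulating the nested and
#' partially redundant pathway annotations (GO parents/children, KEGG vs
#' Reactome versions of one process) that real enrichment maps link into
#' connected clusters. Remaining members are drawn from non-responders.
#' Decoy sets are drawn uniformly from all genes.
#'
#' One RNG stream seeded by `seed` is consumed in a fixed, documented order —
#' responder sampling, noise matrix, planted-set fillers, decoy sets — so the
#' same seed reproduces the same experiment exactly.
#'
#' @param n_genes Number of genes.
#' @param n_responders Number of genes with a trainer-specific response.
#' @param trainer_effect,comparator_effect Log2-unit shifts applied to
#'   responders in the stimulated state of each arm;
#'   `comparator_effect < trainer_effect` makes responders trainer-biased.
#' @param noise_sd Standard deviation (log2 units) of the Gaussian noise
#'   added to every cell; may be 0 for noiseless checks.
#' @param replicates Replicates per (stimulus, state) cell; at least 2.
#' @param n_planted_sets,n_decoy_sets Numbers of planted and decoy gene sets.
#' @param planted_set_size Members per planted (and decoy) set.
#' @param planted_purity Fraction of each planted set drawn from responders,
#'   in (0, 1].
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list of class `training_simulation` with elements
#'   `expression` (an [expression_set()]), `gene_sets` (a tibble in
#'   [read_gmt()] layout), and `truth` (list with `responders`,
#'   `planted_sets`, `decoy_sets`).
#' @export
#'
#' @examples
#' sim <- simulate_training_experiment(n_genes = 200, n_responders = 20,
#'                                     n_decoy_sets = 5, seed = 1)
#' dim(sim$expression)
#' sim$truth$planted_sets
simulate_training_experiment <- function(n_genes = 5000,
                                         n_responders = 200,
                                         trainer_effect = 2.0,
                                         comparator_effect = 0.5,
                                         noise_sd = 0.5,
                                         replicates = 3,
                                         n_planted_sets = 3,
                                         n_decoy_sets = 100,
                                         planted_set_size = 30,
                                         planted_purity = 0.8,
                                         seed = 17) {
  stopifnot(n_genes >= 1, replicates >= 2, noise_sd >= 0,
            n_planted_sets >= 0, n_decoy_sets >= 0)
  if (n_responders > n_genes) {
    abort("Infeasible config: n_responders exceeds n_genes.")
  }
  if (planted_set_size > n_genes) {
    abort("Infeasible config: planted_set_size exceeds n_genes.")
  }
  if (planted_purity <= 0 || planted_purity > 1) {
    abort("Infeasible config: planted_purity must lie in (0, 1].")
  }
  n_core <- round(planted_purity * planted_set_size)
  if (n_planted_sets > 0 && n_core > n_responders) {
    abort("Infeasible config: planted_purity * planted_set_size exceeds n_responders.")
  }
  stride <- max(1L, ceiling(n_core / 2))
  if (n_planted_sets > 0 && (n_planted_sets - 1L) * stride + n_core > n_responders) {
    abort(paste0("Infeasible config: the overlapping planted-set windows need ",
                 (n_planted_sets - 1L) * stride + n_core,
                 " responders but only ", n_responders, " are available."))
  }
  n_filler <- planted_set_size - n_core
  if (n_planted_sets > 0 && n_filler > n_genes - n_responders) {
    abort("Infeasible config: not enough non-responder genes for planted-set fillers.")
  }

  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  ann <- tidyr::expand_grid(stimulus = c("trainer", "comparator"),
                            state = c("baseline", "stimulated"),
                            replicate = seq_len(replicates))
  ann$sample_id <- sprintf("%s_%s_r%d", ann$stimulus, ann$state, ann$replicate)
  ann <- ann[, c("sample_id", "stimulus", "state", "replicate")]

  withr::with_seed(seed, {
    responders <- sort(sample(gene_ids, n_responders))

    mu <- matrix(8.0, n_genes, nrow(ann),
                 dimnames = list(gene_ids, ann$sample_id))
    resp_rows <- gene_ids %in% responders
    mu[resp_rows, ann$stimulus == "trainer" & ann$state == "stimulated"] <-
      8.0 + trainer_effect
    mu[resp_rows, ann$stimulus == "comparator" & ann$state == "stimulated"] <-
      8.0 + comparator_effect
    values <- mu + matrix(rnorm(length(mu), 0, noise_sd), nrow(mu), ncol(mu))

    tags <- c("K", "G", "P", "R")
    planted <- purrr::map(seq_len(n_planted_sets), function(i) {
      core <- responders[((i - 1L) * stride + 1L):((i - 1L) * stride + n_core)]
      filler <- if (n_filler > 0) {
        sample(setdiff(gene_ids, responders), n_filler)
      } else character(0)
      tag <- tags[(i - 1L) %% 4L + 1L]
      tibble(name = sprintf("PLANTED_%02d", i),
             description = "planted trainer-response set",
             source = tag,
             members = list(c(core, filler)))
    })
    decoys <- purrr::map(seq_len(n_decoy_sets), function(i) {
      tag <- tags[(i - 1L) %% 4L + 1L]
      tibble(name = sprintf("DECOY_%03d", i),
             description = "decoy set drawn uniformly from all genes",
             source = tag,
             members = list(sample(gene_ids, planted_set_size)))
    })
  })

  gene_sets <- dplyr::bind_rows(c(planted, decoys))
  if (nrow(gene_sets) > 0) {
    gene_sets$set <- paste0(gene_sets$name, "|", gene_sets$source)
    gene_sets <- gene_sets[, c("set", "name", "source", "description", "members")]
  } else {
    gene_sets <- tibble(set = character(0), name = character(0),
                        source = character(0), description = character(0),
                        members = list())
  }

  truth <- list(
    responders = responders,
    planted_sets = gene_sets$set[grepl("^PLANTED_", gene_sets$name)],
    decoy_sets = gene_sets$set[grepl("^DECOY_", gene_sets$name)]
  )
  structure(list(expression = expression_set(values, ann),
                 gene_sets = gene_sets,
                 truth = truth),
            class = "training_simulation")
}

#' @export
print.training_simulation <- function(x, ...) {
  cat(sprintf("<training_simulation> %d genes, %d samples, %d responders\n",
              nrow(x$expression$values), ncol(x$expression$values),
              length(x$truth$responders)))
  cat(sprintf("  gene sets: %d planted, %d decoy\n",
              length(x$truth$planted_sets), length(x$truth$decoy_sets)))
  invisible(x)
}
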