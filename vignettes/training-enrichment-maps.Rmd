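---
title: "From a two-stimulus expression matrix to a functional enrichment map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a two-stimulus expression matrix to a functional enrichment map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trainmap)
library(dplyr)
```

## The analysis problem

Innate immune cells can be functionally reprogrammed by a first stimulus so
that they respond more strongly to a later, unrelated one — *trained
immunity*. β-glucan trains human monocytes; LPS stimulates them without
training. Contrasting the transcriptional response to a training stimulus
(the *trainer*) against a non-training one (the *comparator*) in a 2×2
factorial design (stimulus × treatment state) isolates the genes whose
response is specifically stronger under training, and summarizing those
genes at the pathway level as a *functional enrichment map* shows which
biological processes carry the training signature.

`trainmap` implements that pipeline end to end:

1. **Quantile normalization** of the gene × sample log2 matrix (for raw
   inputs; array platforms often export already-normalized values).
2. **Response profiling**: per gene and per stimulus, the mean stimulated −
   baseline difference and its signal-to-noise ratio.
3. **K-means clustering** of the per-gene profiles.
4. **Per-gene factorial interaction tests**, BH-adjusted within each
   cluster, and responder selection (significant *and* trainer-biased).
5. **Hypergeometric gene-set enrichment** of the responders against merged
   KEGG/GO/Panther/Reactome collections.
6. **Enrichment-map construction**: significant sets as nodes, overlap
   scores as edges, components labelled with Tarjan's algorithm.

## The statistical model

For one gene with value $y$, state indicator $S$ (1 = stimulated) and
stimulus indicator $T$ (1 = trainer), the factorial model is the ordinary
least-squares fit

$$y = \mu + a\,S + b\,T + c\,ST + \varepsilon,$$

so the comparator response is $a$, the trainer response is $a + c$, and the
interaction $c$ is exactly the difference between the two responses. The
hypothesis of interest, "the two stimuli elicit different responses", is
the partial F-test of $c$ against the additive model, on 1 and $n-4$
degrees of freedom. A *responder* is a gene whose BH-adjusted interaction
p-value is below $\alpha$ **and** whose interaction estimate is positive
(trainer response exceeds comparator response); the two-sided p-value plus
a sign gate mirrors the two-step description of significance followed by
direction. Genes with an exact (zero-residual) fit are assigned p = 0 when
the interaction estimate is non-zero and p = 1 otherwise, with a warning,
instead of propagating NaN.

The BH adjustment is the step-up rule
$q_{(i)} = \min_{j \ge i} p_{(j)} m / j$ capped at 1. By default it is
applied **within each k-means cluster** — each cluster is its own testing
family — with a global-family option (`per_cluster = FALSE`).

Enrichment of a responder list of size $n$ against a set with $K$ members
in a universe of $N$ genes uses the one-sided hypergeometric tail
$P(X \ge k)$, the classic over-representation test for a discrete gene
list. Sets are intersected with the universe before counting, sets with
fewer than 5 or more than 500 in-universe members are excluded (a
conventional guard against unstable tiny or diffuse sets; both bounds are
arguments), and p-values are BH-adjusted across all tested sets as one
merged family. The *enrichment score* is $-\log_{10} p$, with the default
significance gate score > 1.3 (i.e. p < 0.05) applied to the raw p-value;
`use_adjusted = TRUE` switches the gate to the adjusted p-value, which is
always reported alongside.

Map edges carry the *overlap score*, the average of the Jaccard coefficient
$|A \cap B| / |A \cup B|$ and the overlap coefficient
$|A \cap B| / \min(|A|, |B|)$, computed on universe-intersected
memberships; pairs at or above `edge_threshold` (default 0.25, the
conventional cutoff for combined-overlap enrichment maps; the original
threshold is not documented, so it is exposed as a parameter) become edges.
Components are found with Tarjan's single-pass low-link algorithm on the
symmetrized digraph (each undirected edge replaced by two opposed arcs), on
which strongly connected components coincide with connected components;
the implementation is iterative, so component extraction has no recursion
depth limit.

## A worked run on synthetic data

Raw data behind this kind of training experiment are often not deposited,
so the package ships a generator that plants known structure:

```{r simulate}
sim <- simulate_training_experiment(
  n_genes = 2000, n_responders = 150, trainer_effect = 2.0,
  comparator_effect = 0.5, noise_sd = 0.5, replicates = 3,
  n_planted_sets = 3, n_decoy_sets = 50, planted_set_size = 30,
  planted_purity = 0.8, seed = 11
)
sim
```

```{r pipeline}
res <- build_training_map(sim$expression, sim$gene_sets,
                          k = 4, normalize = FALSE)
res
glance(res)
```

```{r inspect}
tidy(res) |> arrange(p_adjusted) |> head()
res$enrichment |> filter(significant) |> arrange(p) |> head()
tidy(res$map)
```

```{r plots, fig.width = 6, fig.height = 5}
autoplot(res$map)
plot_snr_heatmap(res$profiles, res$clusters)
```

## What the generator emulates — and what it does not

Each gene sits at a baseline of 8.0 log2 units (the location cancels in
every downstream contrast, which keeps the planted truth interpretable).
Responder genes gain `trainer_effect` log2 units in the
(trainer, stimulated) cell and `comparator_effect` in the
(comparator, stimulated) cell; every cell receives i.i.d. Gaussian noise.
One RNG stream seeded by `seed` is consumed in a fixed order (responders,
noise, planted sets, decoys), so a seed fully reproduces an experiment.

Planted gene sets draw `round(planted_purity × planted_set_size)` members
from the responders as overlapping windows with a stride of half a window,
so consecutive planted sets share about half their responder core
(overlap score ≈ 0.33). This emulates the nested and partially redundant
annotations — GO parents and children, the KEGG and Reactome versions of
one process — that make real enrichment maps cluster into connected
components. An independent uniform draw of each set's core would give an
expected pairwise overlap score of roughly 0.08 for the default geometry,
which no conventional edge threshold would connect; real curated
collections describing one biological response are far more redundant than
that. Decoy sets are drawn uniformly from all genes, which makes their hit
counts exactly hypergeometric under the null — the decoy false-positive
rate therefore checks the enrichment test's calibration.

The generator deliberately omits: probe- and bead-level noise, batch and
donor effects, correlated noise between genes, heavy-tailed intensity
distributions, and mean–variance dependence. Passing tests on this
synthetic data therefore demonstrate the pipeline's statistical
correctness and its recovery of planted structure under clean Gaussian
conditions — not robustness to the technical artefacts of a real array
study.

## Normalization and the simulated input

The generator's output stands in for the **normalized** gene-level matrix
an array platform exports (bead-level processing and quantile
normalization happen upstream in the vendor software). The planted-truth
evaluations therefore run the pipeline with `normalize = FALSE`.
`quantile_normalize()` remains a first-class stage for raw inputs and is
contract-tested on its own: it forces identical column distributions, is
idempotent, and preserves within-column ranks. Note that quantile
normalization on data whose column distributions genuinely differ for
biological reasons — such as a strong stimulated-arm response concentrated
in a minority of genes — will partially flatten that biology; on the
default simulation it attenuates the median planted interaction from about
1.6 to 0.9 log2 units. That is the method's documented behaviour, and the
reason the evaluation does not re-normalize data that is already on a
common distribution.

## Numerical and design choices

* **Tie handling in quantile normalization**: tied values receive the mean
  of the reference values their rank run spans (computed with cumulative
  sums, so it is exact and order-independent). Idempotence is exact on
  tie-free data; with ties the first pass merges tied reference positions
  and subsequent passes are fixed points only approximately.
* **Signal-to-noise**: $(\mu_1 - \mu_2)/(\sigma_1 + \sigma_2)$ with sample
  standard deviations and the denominator floored at $10^{-8}$, the
  standard definition for expression heatmaps and robust to zero-variance
  genes. The default contrast is stimulated vs baseline within a stimulus;
  `reference = "other_stimulus"` contrasts the two stimulated arms.
* **Clustering**: Lloyd's algorithm with k-means++ seeding, best of
  `restarts` runs (default 10) by within-cluster sum of squares,
  deterministic given `seed` (default 17). Profile dimensions —
  (snr_trainer, snr_comparator, response_trainer, response_comparator) —
  are standardized to zero mean and unit variance so magnitude and
  reliability features weigh equally. An emptied cluster is repaired by
  splitting off the point farthest from its centroid. The default `k = 9`
  suits rich real transcriptomes with many response shapes.
* **Choice of k on planted data**: the synthetic experiments contain
  exactly two true profile classes (responders and background), so the
  planted-truth evaluations use `k = 4`: enough clusters to absorb
  background substructure, but not so many that the single responder class
  fragments across clusters. Fragmentation matters because the BH family
  is the cluster: when the responder class splits by realized effect
  strength, the stronger fragment's small p-values drive its family's
  step-up threshold up while the weaker fragment's family stays stringent,
  biasing selection against whichever planted core lands there.
* **Gene identity**: all gene ids are upper-cased at ingest, because array
  annotations and GMT collections routinely disagree on case; sets with
  the same name from different collections stay distinct as `"name|tag"`.
* **Determinism of outputs**: node and edge tables are sorted in the C
  locale with canonical edge orientation (lexicographically smaller set
  first), so repeated exports are byte-identical.
* **Evaluation problem sizes**: the calibration checks use 10,000 null
  genes; planted-truth recovery uses the generator defaults (5,000 genes,
  200 responders, 3 planted sets, 100 decoys) across 20 seeded runs —
  large enough for stable rates while keeping a full run in seconds.

## Known limitations

* Plain OLS per gene, without moderated (empirical-Bayes) variance
  shrinkage — at 2–3 replicates per cell a moderated test would be more
  powerful; whether the original analysis used one is not documented.
* The universe defaults to all genes on the (normalized) array; an
  expressed-genes universe can be passed explicitly instead.
* Probe-to-gene collapsing is assumed done upstream; the first matrix
  column must already be a gene identifier.
* Recovery of *every* planted set at the default effect sizes is a
  high-power but not certain event: a planted core whose two dozen
  responders happen to draw collectively weak noise realizations can fall
  just short of the selection cutoff in an occasional run.
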