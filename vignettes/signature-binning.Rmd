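---
title: "Signature-based visualization and human-augmented binning: methods and design"
author: "binscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based visualization and human-augmented binning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binscape)
```

## The problem and the method

Assembling a metagenome from a single sample yields thousands of
fragments (contigs or long reads) of unknown origin. Reference-independent
*binning* groups them into population-level clusters using only
data-inherent signal. The signal used here is the *genomic signature*: the
vector of oligonucleotide (k-mer) frequencies of a fragment, which is
characteristic of the genome it came from. For k = 5 and no strand
folding this vector has 4^5 = 1,024 components.

The pipeline is:

1. **Length filter.** Only fragments of at least `minLength` nt (default
   1,000) are considered. Short fragments carry too few k-mer windows for
   a stable signature; cluster overlap grows as lengths approach ~600 nt,
   which the test suite demonstrates on synthetic data.
2. **Signatures.** Overlapping k-mer windows consisting solely of A/C/G/T
   are counted (windows touching N or any other IUPAC ambiguity code are
   skipped, deterministically, rather than randomized). Counts receive an
   additive pseudocount (default 1) and are normalized to frequencies.
3. **Centered log-ratio (CLR) transform.** Frequencies are compositional
   (they sum to 1); Euclidean geometry on the simplex is misleading. CLR,
   `ln(x_i) - mean_j ln(x_j)`, maps each signature to an unconstrained
   vector summing to zero. The pseudocount exists precisely because CLR
   is undefined at zero counts.
4. **PCA pre-reduction** (optional, default 50 components) before the
   embedding, standard practice for Barnes-Hut t-SNE. Disable with
   `pcaDims = NULL`.
5. **Barnes-Hut t-SNE** maps the signatures to 2-D. Gaussian conditional
   affinities are calibrated per point to a target perplexity;
   symmetrized joint affinities are matched against a Student-t kernel in
   the embedding by gradient descent on the Kullback-Leibler divergence.
   The repulsive force field is approximated with a quadtree.
6. **Human-augmented binning.** Clusters apparent to the eye are
   delineated with polygons (drawn in any external viewer over the saved
   `embedding.csv`, or supplied as files); enclosed sequences are
   exported as FASTA bins.
7. **Bin assessment.** Bins are scored against a universe of 107
   bacterial single-copy essential genes: *completeness* is the fraction
   of the universe present at least once; genes present in two or more
   copies signal a mixed (contaminated) bin.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `minLength` | 1000 nt | inclusive length filter before signatures |
| `k` | 5 | k-mer length; dimensionality 4^k |
| `mergeRevcomp` | `FALSE` | fold reverse complements onto canonical k-mers (512 for k = 5). Off by default to preserve the full 4^k signature; strand folding is common practice and exposed as an option |
| `pseudocount` | 1 | additive smoothing before normalization |
| `pcaDims` | 50 | PCA components before t-SNE; `NULL` disables |
| `perplexity` | 30 | effective neighbor count; each point stores floor(3 × perplexity) exact nearest neighbors |
| `theta` | 0.5 | Barnes-Hut accuracy; 0 is the exact method |
| `nIter` | 1000 | gradient-descent iterations |
| `earlyExaggeration` | 12 (first 250 iters) | inflates attractive forces early so clusters can separate |
| `learningRate` | 200 | with per-parameter adaptive gains |
| momentum | 0.5 → 0.8 at iter 250 | reference-implementation schedule |
| `seed` | — | fixed seed + 1 thread ⇒ bit-identical embedding |

The t-SNE defaults follow the reference Barnes-Hut implementation; none
are data-dependent.

## Numerical choices

* **Perplexity calibration.** Per-point precision `beta_i` is found by
  bisection until the Shannon entropy of the conditional distribution is
  within 1e-5 bits of `log2(perplexity)` (at most 200 iterations). If all
  neighbor distances of a point are zero, its conditionals fall back to
  uniform. Nearest neighbors are exact, with distance ties broken by row
  index, so results are seed-reproducible.
* **Neighbor count.** `floor(3 * perplexity)` neighbors are stored,
  capped at n − 1; the cap makes small degenerate instances (e.g. four
  equidistant points) well defined. Only `perplexity > n - 1` is an
  error.
* **Floors.** `p` and `q` are floored at 1e-12 inside logarithms only;
  forces never use floored values.
* **Barnes-Hut.** A quadtree cell of width w at distance r is summarized
  by its center of mass when w/r < theta. Coincident points beyond
  depth 48 share a leaf and are handled exactly. The global Student-t
  normalizer Z is accumulated per point and reduced in fixed order, so
  the gradient is bitwise independent of thread count.
* **Initialization.** Y ~ Gaussian(0, 1e-4) from one RNG stream seeded by
  `seed`. An explicit `Y0` can be supplied instead (continuation runs,
  equivariance checks). We do not key the stream per row: permutation
  equivariance of a full optimization trajectory is unattainable anyway,
  because reordered floating-point summation is amplified by hundreds of
  gradient steps. The invariant is tested where it is mathematically
  meaningful — affinities and single gradient evaluations are
  permutation-equivariant to ≤ 1e-9.
* **PCA sign convention.** Each component is flipped so its
  largest-magnitude loading is positive, making the projection unique.
* **Divergence aborts.** Non-finite gradients or coordinates abort with a
  diagnostic; nothing is silently clipped.
* **Polygon membership** uses the even-odd (ray-casting) rule;
  self-intersecting polygons are allowed, and points exactly on an edge
  or vertex count as inside — a drawn boundary captures the points under
  it. Disjoint polygons therefore partition points, except for points
  exactly on a shared edge, which both capture.
* **Visual encodings.** Size is min-max-scaled `ln(length)` into
  [2, 12] display units, opacity is `ln(coverage + 1)` into [0.2, 1]
  (the +1 guards coverage-0 contigs); "proportional to the logarithm"
  fixes only the monotone-linear-in-log shape, not the range. Degenerate
  channels (all values equal) collapse to the range minimum.
* **Copy counting.** A gene occurring twice on one contig counts as copy
  number 2 — occurrences, not carrier contigs — the
  contamination-sensitive convention. `totalMbp` is rounded half-even to
  two decimals at report time only.
* **Annotation alignment** is positional: the file carries no id column,
  so row i describes FASTA record i (before filtering); rows are then
  subset to the retained records. This is a documented convention of the
  format, not inferred from ids.

## The synthetic-data generator

Real mock communities require external downloads; the generator instead
produces communities with exactly the statistical structure
signature-based binning assumes: population-specific oligonucleotide
composition.

Each population is an order-4 Markov source over A/C/G/T (order 4 so that
5-mer signatures are informative by construction). Transition rows are
log-normally perturbed uniform compositions,
`p(base | context) ∝ exp(divergence × 0.2 × z)`, `z ~ N(0, 1)`:
`divergence = 0` makes all populations identical and 1 gives
multiplicative composition biases of about e^±0.2. The fixed scale 0.2
was calibrated once so that the default study conditions (5 populations,
divergence 0.8, 200 fragments per population) reproduce the known length
dependence of the method: fragments ≥ 1,000 nt embed into clusters
recoverable at ≥ 0.9 five-NN label purity, while ~600-nt fragments
overlap visibly and score lower. Fragment lengths are
`fragMin + Exp(fragMean − fragMin)`; per-population coverage is
log-normal (median 15×), giving the opacity channel realistic structure;
each of the 107 bundled gene names is planted exactly once per genome on
a random fragment, so completeness and contamination tests have exact
expected values.

What the generator does **not** emulate: within-genome compositional
heterogeneity (rRNA operons, mobile elements, skew along the replichore),
shared composition between related taxa, strain microdiversity, assembly
artifacts (chimeras, repeat-collapsed contigs), or read-level error.
Passing tests therefore show the pipeline recovers structure when the
signature assumption holds cleanly; they do not bound performance on real
assemblies, where these nuisances blur cluster boundaries further.

The bundled gene list (`inst/extdata/essential_genes_synthetic.txt`) is a
representative, synthetic stand-in for the conventional 107-gene
single-copy universe: the names fix the completeness denominator and make
fixtures reproducible, but carry no HMM models. Real analyses should feed
the contig-to-gene table their own annotation pipeline produced
(`readMarkerTable()` accepts any gene universe).

## Problem sizes in the test suite

The packaged tests run communities of 5 × 200 fragments (~1,000 embedded
points) for cluster-recovery checks, n = 300 instances for gradient
oracle equivalence, n = 500 for perplexity calibration, and 1,000 random
sequences for the k-mer oracle — sizes chosen so the full suite completes
in a few minutes on one core while each check still exercises the regime
it is about (e.g. quadtree summarization only matters once n is a few
hundred).

## Known limitations

* Exact kNN is all-pairs (O(n²) memory in the distance matrix); the
  intended scale is tens of thousands of fragments, not millions.
* 2-D embeddings only; no 3-D output.
* Binning is deliberately human-in-the-loop: no automatic cluster
  detection is provided, only polygon selection.
* Coverage is consumed from the annotation file; the package does not map
  reads.
* t-SNE distances between clusters are not quantitatively meaningful;
  the embedding supports delineation, not phylogenetic inference.
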