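---
title: "Positional correlation natural vectors: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional correlation natural vectors: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnv)
```

## The problem

Whole-genome phylogenetics and viral genotyping are routinely blocked by the
cost of multiple sequence alignment: for hundreds of viral genomes, or for
bacterial genomes of megabase size, alignment is the bottleneck and often
infeasible. Alignment-free methods sidestep it by mapping every sequence to a
fixed-length numeric summary and comparing summaries instead of aligned
columns. This package implements one such summary, the positional correlation
natural vector (PCNV), and the downstream steps a genotyping study needs:
distance matrices, neighbor-joining trees, and nearest-neighbor
classification.

## The descriptor

For a DNA sequence $S = s_1 s_2 \dots s_N$ and a nucleotide
$\alpha \in \{A, C, G, T\}$ occurring $n_\alpha$ times at 1-based positions
$p_{\alpha 1} < \dots < p_{\alpha n_\alpha}$ (with the convention
$p_{\alpha 0} = 0$), the *positional distribution* is the step function

$$
U_\alpha(i) =
\begin{cases}
\dfrac{p_{\alpha j}}{p_{\alpha,j+1} - p_{\alpha j}}, &
  p_{\alpha j} \le i < p_{\alpha,j+1},\ j = 0, \dots, n_\alpha - 1,\\[1ex]
\dfrac{p_{\alpha n_\alpha}}{N - (p_{\alpha n_\alpha} - 1)}, &
  p_{\alpha n_\alpha} \le i \le N.
\end{cases}
$$

Within each block between consecutive occurrences the value is constant, so
$U_\alpha$ can be built in $O(n_\alpha)$ block operations; the package does
this (`positional_distribution()`), while the test suite keeps a literal
per-position scan as an independent oracle. A useful identity falls out of
the block structure: $\sum_i U_\alpha(i) = \sum_j p_{\alpha j}$, so the
*average positional distribution*

$$\kappa_\alpha = \frac{1}{n_\alpha} \sum_{i=1}^{N} U_\alpha(i)$$

is exactly the arithmetic mean of the occurrence positions. Both identities
are enforced as property tests. Second-order structure is captured by the
*positional covariance*

$$\mathrm{cov}(\alpha, \beta) =
  \frac{1}{n_\alpha n_\beta} \sum_{i=1}^{N}
  \bigl(U_\alpha(i) - \bar U_\alpha\bigr)\bigl(U_\beta(i) - \bar U_\beta\bigr),
\qquad \bar U_\alpha = \frac{1}{N}\sum_i U_\alpha(i),$$

and the *positional variance* $D^2_\alpha = \mathrm{cov}(\alpha, \alpha)$.
Note the denominator is $n_\alpha n_\beta$, not $N$: this is unusual for a
covariance, but it is the definition the descriptor is built on; the hand-checked
worked value for the 9-nt example sequence `ACTGGCAAT` is
$\mathrm{cov}(A, C) = 1.4769$, and the package reproduces it:

```{r worked}
v <- compute_pcnv("ACTGGCAAT")
round(v[["covAC"]], 4)
```

The full descriptor is the ordered 18-vector

$$(n_A, n_C, n_G, n_T,\ \kappa_A, \dots, \kappa_T,\ D^2_A, \dots, D^2_T,\
\mathrm{cov}(A,C), \mathrm{cov}(A,G), \mathrm{cov}(A,T),
\mathrm{cov}(C,G), \mathrm{cov}(C,T), \mathrm{cov}(G,T)),$$

and sequences are compared by plain Euclidean distance between their
vectors, with no component scaling.

## Edge cases and numerical choices

* **Absent nucleotide** ($n_\alpha = 0$). The defining sums divide by
  $n_\alpha$, so the package defines $\kappa_\alpha = D^2_\alpha = 0$ and
  every covariance involving $\alpha$ as 0. Zero is the natural "no signal"
  value, matches the all-zero $U_\alpha$, and keeps every vector finite.
* **Ambiguous IUPAC letters** (N, R, Y, ...). Real GenBank genomes contain
  them, but the descriptor is defined over A, C, G, T only. By default an
  ambiguous letter occupies its position — so the coordinates of every later
  base are unchanged — while joining no nucleotide's position list. This
  preserves positional semantics without silently editing the genome.
  `strict = TRUE` (CLI: `--ambiguity strict`) rejects such letters instead.
  RNA input is accepted by mapping U to T in the default mode.
* **Degenerate inputs.** A length-1 sequence is valid
  ($U = p_1 / (1 - (p_1 - 1)) = 1$ for its single base); the empty sequence
  is an error. Lowercase is uppercased on read (soft-masking convention).
* **Arithmetic.** Double precision throughout. Internal identities are
  tested at absolute tolerance 1e-9; the comparison against the 4-decimal
  printed value 1.4769 uses 5e-5.

## Tree building

Distance matrices feed canonical Saitou–Nei neighbor joining. NJ is often
delegated to GUI software in practice; this package implements
standard NJ itself so the pipeline is self-contained and the algorithm is testable
against an exact oracle: on any additive matrix (one realizable as path
lengths on a tree), NJ must recover the generating topology and reproduce
every leaf-to-leaf distance. The test suite checks this on hundreds of
random trees of up to 8 taxa at tolerance 1e-9, and additionally
cross-checks topologies and branch lengths against `ape::nj` on noisy
(non-additive) matrices.

Two behaviors are pinned down that the NJ literature leaves open:

* **Tie breaking.** When several pairs minimize the Q-criterion, the lowest
  (i, j) pair in current matrix order is joined, making the output
  deterministic (verified by the permutation-invariance test).
* **Negative branch lengths.** NJ can produce them on non-additive input.
  They are clamped to 0 by default — the common rendering convention — with
  the pre-clamp values retained in the `clamped` attribute of the returned
  tree; `allow_negative = TRUE` (CLI: `--allow-negative`) disables clamping.

Trees are serialized to Newick by an in-package writer that quotes labels
containing structural characters (spaces, parentheses, commas), because
`ape::write.tree` substitutes such characters instead of quoting.

## Classification protocol

Genotype prediction is one-nearest-neighbor on the Euclidean distance
matrix. The evaluation protocol is leave-one-out: each record takes the
class of its nearest neighbor excluding itself — the standard protocol for
evaluating 1-NN on a single dataset, and this package's documented choice.
Per class $c$, one-vs-rest counts give
$\mathrm{Sens} = TP/(TP+FN)$ and $\mathrm{Spec} = TN/(FP+TN)$. Per-class
accuracy is implemented as the fraction of the class's members predicted
correctly, which equals sensitivity under one-vs-rest tabulation, and an
overall accuracy (total correct / total records) is reported separately as
a clearly labeled extension. The "Ave." row is the unweighted mean over
classes; classes with no true members yield NA and are excluded from the
averages with a warning. Nearest-neighbor ties go to the smallest matrix
index, and a class with a single member is flagged with a warning since its
member can never be predicted correctly under leave-one-out.

## What the simulator emulates

`make_clusters()` generates `n_clusters` independent uniform-random
ancestors and, per ancestor, `per_cluster` descendants by independent
per-site substitution at rate `sub_rate` (a hit always changes the base).
Defaults — 4 clusters, 10 descendants each, 5000 nt, rate 0.01 — emulate a
small viral genotyping panel: genome-scale sequences, tight intra-genotype
clusters, unrelated genotypes. The substitution-only model keeps the
expected ancestor–descendant Hamming distance exactly
`sub_rate * length`, which the tests check against binomial 5-sigma bounds;
there are no indels, no rate heterogeneity, no transition/transversion bias
and no recombination. Each record's sequence is driven by its own seed
derived arithmetically from the master seed and the record's position, so a
dataset is bit-reproducible and adding clusters never changes earlier
clusters.

Because ancestors are unrelated and mutations are sparse, within-cluster
PCNV distances are far below between-cluster distances, and leave-one-out
1-NN classification of the default panel is 100% correct in sensitivity,
specificity and accuracy for every class — the package's end-to-end check.
Passing it shows the pipeline is internally consistent and that well
separated clusters are perfectly recovered; it does *not* show that real
genotypes, which differ by structured and sometimes recombinant variation,
are equally separable. Running real HCV/HBV/dengue/HPV/bacteria panels
requires downloading those genomes; the CLI supports such runs, but no
bundled check depends on network access.

## Problem sizes used in the checks

The bundled verification runs use: 1000 random sequences of lengths 1–200
for the oracle-equivalence and mean-identity properties; 200 random
additive matrices of up to 8 taxa for NJ consistency; and the default
4 x 10 x 5000 nt simulated panel for the end-to-end classification check.
These sizes give stable statistics while keeping a full test run under a
minute on a single CPU; the vectorizer itself is linear in sequence length
and handles megabase bacterial genomes.

## Known limitations

* The 18 components live on very different scales (counts grow with $N$,
  covariances do not); the Euclidean distance is deliberately unweighted,
  as defined, so longer genomes weigh count differences more heavily.
* The covariance normalization by $n_\alpha n_\beta$ makes the descriptor
  length-sensitive; comparing sequences of very different lengths mixes
  length signal with compositional signal.
* NJ output on non-additive matrices depends on the documented tie and
  clamping rules; bit-identical agreement with other NJ implementations on
  such input is not guaranteed (branch lengths agree, topology agrees in
  our cross-checks, but tie handling may differ on exactly degenerate
  input).
* The simulator's i.i.d. substitution model is a testing instrument, not an
  evolutionary model.
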