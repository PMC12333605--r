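---
title: "Methods: similarity-based microbe-drug association prediction with a convolutional encoder and a Bernoulli random forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-based microbe-drug association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Known microbe-drug associations form a sparse bipartite graph: an adjacency
matrix $A \in \{0,1\}^{n_d \times n_m}$ over $n_d$ drugs and $n_m$
microbes, with $A_{ij} = 1$ when drug $d_i$ is known to act on microbe
$m_j$. Curated collections of such associations are small relative to the
$n_d \times n_m$ grid (a fraction of a percent), and the unlabeled pairs
are a mix of true negatives and undiscovered positives. The task is to
rank unlabeled pairs so that plausible new associations surface at the
top, where they can guide repurposing screens.

The premise the model exploits is smoothness over similarity: drugs with
similar chemical structures and side-effect profiles tend to act on the
same microbes, and microbes with similar genomic sequences tend to respond
to the same drugs. Every stage of the pipeline is a consequence of that
premise.

## Integrated similarities

Two sources of drug similarity are combined:

* **Side-effect Jaccard** ($SS1$): each drug carries a set $N(i)$ of
  side-effect terms; $SS1(i,j) = |N(i) \cap N(j)| / |N(i) \cup N(j)|$,
  with 0 when the sets share nothing (including when either is empty), and
  unit diagonal.
* **Chemical-structure similarity** ($SS2$): a precomputed graph-matching
  score matrix is taken as input. Off-diagonal scores strictly below a
  cutoff (default 0.5) are zeroed; surviving scores stay continuous. A
  `binarize` flag maps survivors to 1 instead, for users who prefer a hard
  neighborhood graph; continuous is the default because the downstream
  features are themselves continuous similarities.

The integrated drug similarity is the elementwise mean
$SD = (SS1 + SS2)/2$. When a drug has no side-effect record, the literal
average halves its structure similarity; this is the default because the
averaging rule is applied uniformly, with no reweighting by data
availability. An `available` mode instead averages only over sources with
data ($SD = SS2$ for pairs involving a drug with no side-effect record),
for sensitivity analyses. Microbe similarity is used as-is:
$SM = MV$, the sequence-identity matrix. No Gaussian-kernel similarity is
computed anywhere; the model deliberately uses only the raw evidence
sources.

Entities present in the association table but absent from a similarity
file get a zero off-diagonal row/column with unit diagonal — the same
"absent evidence scores zero" convention the Jaccard uses. Similarity
diagonals are always forced to 1 on load: features are rows of these
matrices, and self-similarity 1 makes a pair's own identity visible to the
downstream learner.

## Pair features

The feature vector of pair $(d_u, m_v)$ is the concatenation of microbe
row $v$ of $SM$ (length $n_m$) and drug row $u$ of $SD$ (length $n_d$):
microbe block first, then drug block, total $n_m + n_d$. The layout is
tagged on every feature matrix so a transposed layout can never silently
reach the encoder. Features depend only on the similarity matrices, never
on $A$; labels enter exclusively through the training set, which keeps the
held-out fold information out of the representation.

Training sets are balanced 1:1 — all known associations as positives, an
equal number of sampled unlabeled pairs as negatives. This treats
unlabeled pairs as negatives, which is defensible because positives are a
tiny fraction of the grid; the mislabeling risk is the price of having any
negatives at all. Two samplers are provided:

* **Uniform**: negatives drawn uniformly without replacement.
* **Density-aware stratified (DAS)**: each unlabeled pair's density is the
  number of other pool members within a radius in feature space; the pool
  is sorted by density (descending, ties by enumeration index) and sampled
  at fixed intervals $\lfloor k\,|pool|/n \rfloor$, $k = 0..n{-}1$, so all
  density strata are represented. Distance is Euclidean on raw pair
  features. The default radius is the 25th percentile of pairwise
  distances in a seeded subsample of $\min(1000, |pool|)$ points — a
  percentile scales with feature dimension where a fixed constant would
  not. For pools beyond a cap (default 20,000) densities are counted
  against a seeded reference subsample in chunks; only the density
  *ordering* matters to systematic sampling, so the estimate is adequate,
  and an exact mode exists behind a flag.

During cross-validation the sampling pool deliberately includes held-out
positives (they are unlabeled from the training view); excluding them
would leak the test set into training-time decisions.

## The convolutional encoder

Pair vectors of length $n_m + n_d$ are compressed to
$\lfloor (n_m + n_d)/2 \rfloor$ dimensions by a small one-dimensional
convolutional network with exactly three trainable layers:

| layer | shape | notes |
|---|---|---|
| conv1d | 16 filters, width 16, stride 1, valid padding | ReLU |
| max-pool | width 2, stride 2 | |
| dropout | rate 0.5 | training only |
| dense | $\lfloor (n_m+n_d)/2 \rfloor$ units | ReLU; **the embedding** |
| dropout | rate 0.5 | training only |
| dense | 1 unit | sigmoid; training head |

The head is trained with minibatch Adam (learning rate $10^{-3}$, batch
size 32, 20 epochs by default) on binary cross-entropy against the
balanced training labels, then discarded: the penultimate dense layer's
activations are the pair embedding. A flag exposes the head's probability
for a CNN-only baseline. Filter counts and widths are the architecture's
fixed identity; stride 1 with valid padding is chosen because the
network's purpose is compression — padding would manufacture positions
that correspond to no similarity entry. Dropout rate, batch size, and
learning rate are conventional defaults, all exposed in `encoder_config()`.

Initialization, shuffling and dropout all derive from one seed;
inference runs without dropout, so encoding is deterministic and row-wise
(each row's embedding depends only on that row). Training that ends with a
higher loss than it started with triggers a warning, not an error — on
very short runs this is expected and harmless. For a 1,373-drug,
173-microbe study the input length is 1,546 and the embedding width 773;
for 1,720 drugs and 140 microbes, 1,860 and 930. Both reference scales are
even; an odd input takes the floor.

## The Bernoulli random forest

The scorer is a from-scratch Bernoulli random forest (BRF), a random
forest variant with three structural differences that jointly support
consistency arguments while keeping empirical behavior close to a
classical forest:

1. **Structural/estimation split.** Each tree's (bootstrapped) sample is
   divided once — default half and half, round half up — into a
   *structural* part that chooses all splits and a disjoint *estimation*
   part that only fills leaf class fractions. Flipping estimation labels
   provably cannot change tree shape, a property the test suite asserts by
   hashing tree structure.
2. **Trial B1 — candidate features.** At each node, with probability
   $p_1$ a single uniformly drawn feature is the only candidate; otherwise
   $\lceil \sqrt{D} \rceil$ distinct features are drawn.
3. **Trial B2 — split point.** With probability $p_2$ the threshold is
   drawn uniformly inside a candidate's value range at the node; otherwise
   the split minimizes weighted Gini impurity
   $\sum_{s \in \{L,R\}} \frac{n_s}{n} \, 2 f_s (1 - f_s)$ over all
   candidates and all midpoints between consecutive distinct sorted
   values.

Defaults: 100 trees, $p_1 = p_2 = 0.05$, minimum 10 structural samples to
split, depth cap 25, bootstrap on. Small trial probabilities keep trees
near-deterministic while retaining the Bernoulli mechanism; both are fully
configurable for sensitivity sweeps. Routing sends
$x_{\text{feature}} \le \text{threshold}$ left; impurity ties break on
lowest feature index, then smallest threshold, making fits reproducible.
A leaf that receives no estimation sample inherits the fraction of the
nearest ancestor that has one (root fallback: the global estimation
fraction). A random threshold that fails to separate the structural
samples simply closes the node as a leaf.

Setting $p_1 = p_2 = 0$, bootstrap off, and `structural_fraction = 1`
(an explicit shared-sample mode) collapses a BRF tree to a classical
CART-style Gini tree with $\lceil \sqrt{D} \rceil$ candidates — the test
suite verifies node-for-node equality against an independently implemented
reference on small instances, which pins down every convention above.

The prediction for a sample is the mean over trees of the positive
fraction of the leaf it reaches. Each tree consumes an RNG stream derived
from the forest seed and its own index, so forests are reproducible and
trees are independent given the seed.

## Evaluation protocol

Cross-validation follows the rank-against-unlabeled convention for
bipartite link prediction:

* Known associations are shuffled (seeded) and split into 5 near-equal
  folds; each fold in turn is zeroed out of the training view.
* The pipeline (sampler, encoder, forest) is trained on the view and
  scores **all** $n_d \times n_m$ pairs.
* The fold AUC is the Mann-Whitney probability that a held-out positive
  outscores a pair unlabeled in the *full* dataset, ties counted one half.
  Tie handling matters: small forests produce heavily tied scores, and
  half-credit is what makes the constant scorer land exactly at 0.5. The
  negative pool retains the training-sampled negatives (they are unlabeled
  pairs too); an `exclude_sampled` mode drops them for comparison.
* The whole procedure repeats (default 10 times) with fold assignments
  re-randomized, and the summary is the mean and population SD over all
  fold AUCs. An alternative mode takes the SD over repeat means; it is
  behind a flag because the two differ systematically (within-repeat
  variance is averaged out of the latter).

One master seed fans out to every stage (folds, samplers, encoder
initialization and shuffling, per-tree streams) through a stable string
hash, so a single integer pins the entire experiment; two runs with the
same seed produce byte-identical score files.

Precision-recall curves are computed at every distinct score threshold.
The encoded-feature correlation diagnostic reports the Pearson correlation
matrix of embedding columns and the distribution of absolute off-diagonal
values (constant columns are flagged and scored 0) — low values indicate
the embedding is not redundant. The case-study workflow masks one drug's
known associations, retrains, and ranks that drug's candidate microbes
top-$k$ (ties broken by microbe index); recovery of the masked associates
measures cold-start performance on a genuinely new drug.

## The synthetic study

The generator plants the exact structure the model assumes. Drugs and
microbes are partitioned into matching blocks; associations are Bernoulli
draws (within-block probability 0.3, background 0.01 by default);
similarities are 0.8 within block, 0.1 across, plus symmetric uniform
noise (half-width 0.05), clipped to $[0,1]$ with unit diagonal;
side-effect profiles give each block a core term set (kept with
probability 0.8 per drug) plus rare private terms, so the Jaccard matrix
also tracks blocks. The default condition is 120 drugs x 40 microbes in 4
blocks — large enough that a fold holds ~80 positives, small enough that a
full CV runs in about a minute. A block model is the right null object
here because "similar entities share associations" *is* a block/cluster
assumption; a latent-factor generator would test a subtly different
premise.

What the generator does **not** emulate: the heavy-tailed degree
distributions of curated databases, correlated noise between the two drug
similarity sources, and systematically missing side-effect coverage.
Passing the planted-structure tests therefore shows the pipeline
preserves recoverable similarity signal end to end — not that it attains
any particular accuracy on real curated data.

A label-shuffle control keeps the association count but places the ones
uniformly at random; the pipeline's AUC on it should be statistically
indistinguishable from 0.5, and the suite asserts this within 0.05.

## Problem sizes and numerical choices

The test suite and the acceptance script run the default synthetic
condition with 2 repeats x 5 folds for the signal measurement and 1 x 5
for the DAS and shuffled-label measurements — enough folds for a stable
mean at desk scale. Representative numbers from one seeded acceptance run:
planted-structure mean AUC 0.864 (SD 0.023), DAS 0.861, shuffled 0.490,
masked-drug recovery 0.84-0.93 depending on seed.

Other numerical details, all deliberate:

* Similarity files are symmetrized as $(S + S^\top)/2$ when asymmetry is
  at most $10^{-6}$ and rejected beyond that; values outside $[0,1]$ by
  more than $10^{-9}$ are errors, smaller excursions are clipped.
* Matrix writers emit 17 significant digits so save/load round trips are
  bit-exact.
* Sigmoid outputs are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the
  cross-entropy; non-finite loss aborts with advice to lower the learning
  rate.
* `round half up` is used wherever a fraction of a sample count must
  become an integer (structural split), avoiding banker's rounding
  surprises.
* All catalogs are 1-based internally, identifiers (never indices) appear
  in files.

## Known limitations

* The similarity inputs are trusted as given; no attempt is made to
  recompute structure or sequence similarity from raw chemistry or
  sequences.
* Balanced 1:1 sampling discards most unlabeled pairs each run; rankings
  for drugs with very few similar neighbors rest on little evidence.
* The encoder is a fixed small architecture; it compresses, it does not
  search architectures. On studies where $n_m + n_d$ is below the kernel
  width (16) it refuses to build, by design.
* BRF consistency arguments concern the infinite-data limit; at desk
  scale the practical benefit is the estimation/structural firewall and
  the reproducible, auditable tree construction.
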