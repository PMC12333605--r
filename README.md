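# mdapredict

Ranking unobserved microbe–drug associations from known associations and
similarity evidence.

Curated microbe–drug association collections are sparse bipartite graphs:
an adjacency matrix $A \in \{0,1\}^{n_d \times n_m}$ with a handful of
known positives scattered over a large grid of untested pairs. For
researchers prioritizing repurposing candidates — which untested microbe
is most likely to respond to this drug? — `mdapredict` turns two kinds of
side evidence (drug similarity from chemical structure and shared side
effects, microbe similarity from sequence identity) into a ranked list of
candidate pairs.

## Method

The pipeline has three stages:

1. **Integrated similarity.** Drug similarity
   $SD = (SS1 + SS2)/2$, where $SS1$ is side-effect Jaccard
   ($|N(i)\cap N(j)| / |N(i)\cup N(j)|$, zero when nothing is shared) and
   $SS2$ is a precomputed chemical-structure score matrix with
   off-diagonal entries below a cutoff (default 0.5) zeroed. Microbe
   similarity $SM$ is the sequence-identity matrix as-is.
2. **Pair encoding.** Each pair $(d_u, m_v)$ is the concatenation
   $[SM_{v\cdot},\, SD_{u\cdot}]$ of length $n_m + n_d$. A small 1-D
   convolutional network (16 filters of width 16, max-pool 2, two dense
   layers, dropout, Adam on binary cross-entropy over a balanced 1:1
   positive/negative sample) compresses every pair vector to
   $\lfloor (n_m + n_d)/2 \rfloor$ dimensions via its penultimate layer.
3. **Bernoulli random forest.** A from-scratch forest in which each tree
   splits its sample into a *structural* part (shapes the tree) and an
   *estimation* part (fills leaf class fractions), and two Bernoulli
   trials inject controlled randomness: B1 picks 1 vs
   $\lceil\sqrt{D}\rceil$ candidate features (probability $p_1$), B2 picks
   a uniform-random vs Gini-optimal split point (probability $p_2$). The
   score of a pair is the mean leaf positive-fraction across trees.

Evaluation follows the rank-against-unlabeled protocol: repeated five-fold
cross-validation over the known associations, scoring held-out positives
against all unlabeled pairs with a tie-aware Mann–Whitney AUC. Negative
sampling is uniform or density-aware stratified (DAS). A masked-drug
workflow measures cold-start ranking for a drug with no training
associations. All of it is driven by one master seed.

## Worked example

A seeded synthetic study with planted block structure (similar drugs and
microbes share associations) exercises the whole pipeline:

```r
library(mdapredict)

synth <- generate_synthetic(synthetic_spec(nd = 60, nm = 20, n_blocks = 4, seed = 7))
sims  <- build_similarities(synth$dataset, synth$structure_sim,
                            synth$profiles, synth$microbe_sim)
synth$dataset
#> <association_dataset: 60 drugs x 20 microbes, 112 associations>

cv <- cross_validate(synth$dataset, sims,
                     cv_config(n_repeats = 1, encoder = list(epochs = 10),
                               brf = brf_config(n_trees = 50), master_seed = 7),
                     keep_curves = FALSE)
cv
#> <cv_result: 1 repeats x 5 folds, AUC 0.8900 +/- 0.0221>
```

The AUC is the probability that a held-out known association outscores a
random unlabeled pair — 0.89 here means the planted similarity signal
survives encoding and forest scoring. Ranking candidates for one drug:

```r
pipe <- train_pipeline(synth$dataset, sims, encoder_args = list(epochs = 10),
                       brf_cfg = brf_config(n_trees = 50), seed = 7)
rank_microbes_for_drug(pipe, synth$dataset, sims, "drug_001", k = 3)
#>   rank     microbe     score
#> 1    1 microbe_004 0.7132715
#> 2    2 microbe_003 0.6803581
#> 3    3 microbe_001 0.6771345
```

Scores are leaf-fraction averages in [0, 1]; microbes already associated
with `drug_001` are excluded from the candidate list.

Real studies are loaded from plain text instead of generated:
`load_association_table()` (TSV/CSV edge list), `load_similarity_matrix()`
(square CSV), `load_side_effects()` (two-column TSV) — see
`vignettes/mdapredict-methods.Rmd` for the file conventions, every tunable
parameter, and the reasoning behind the defaults. A thin command-line
wrapper lives at `inst/cli/mdapredict.R`
(`Rscript inst/cli/mdapredict.R synth --nd 120 --nm 40 --out fixtures/`,
`... pipeline --config run.yaml`, `... cv`, `... rank --drug <id>`).

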