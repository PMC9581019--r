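---
title: "Calibrated co-expression networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated co-expression networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calgcn)
```

This vignette records how `calgcn` implements each stage of the calibrated
gene co-expression network workflow, which choices were genuinely open, and
what the synthetic benchmark does and does not demonstrate.

## The procedure

Given a samples × genes matrix `G` of raw, positive expression values, the
four pipelines share this skeleton:

1. **Calibration** (`calibrate`, skipped by the Pearson baseline):
   `s_ij = plogis((g_ij - mu_j) / sigma_j^2)` per gene `j`.
2. **Similarity** (`innerprod_similarity`, `cosine_similarity`,
   `pearson_minmax_similarity`): a symmetric genes × genes matrix in [0, 1].
3. **Soft threshold** (`pick_soft_threshold`, `power_adjacency`): raise the
   similarities to the smallest integer power whose weighted-degree
   distribution meets a scale-free fit criterion.
4. **Topological overlap** (`tom`, pipelines gamma and wgcna only).
5. **Clustering** (`average_linkage`, `dynamic_tree_cut`) on
   `1 - weight`.
6. **Evaluation** (`score_modules`): exact hypergeometric enrichment,
   five smallest p-values per module, `Q = -mean(log10 p)`, averaged to
   `Q_bar` per pipeline.

The pipelines differ *only* in steps 1–4, which is what makes their module
qualities comparable.

## Calibration: assumptions and numerics

The logistic argument divides by the per-gene **variance**, not the
standard deviation. This is deliberate and pinned by a regression test:
dividing by sigma would make the transform scale-free, whereas the variance
divisor keeps the gene's dynamic range, in its original units, part of the
signal. A consequence worth knowing: on data whose per-gene variance is
far above 1 (e.g. raw linear-scale intensities spanning thousands), the
argument shrinks toward 0 and all calibrated values crowd around 0.5,
compressing every downstream similarity toward 1. The method is therefore
most informative on matrices whose per-gene dispersion is of order one —
log-scale intensities, for instance. The package applies no transform
itself: values are used exactly as deposited, and the loader rejects
missing values unless per-gene mean imputation is requested.

Numerical choices:

* variance is the unbiased sample estimate (divisor m − 1) by default,
  switchable to the population estimate (`var_estimator`);
* the logistic is evaluated through `plogis` (numerically stable for
  extreme arguments) and clamped to `[1e-12, 1 - 1e-12]`, so strict
  positivity survives floating point and downstream norms and logs are
  safe;
* a zero-variance (constant) gene is a hard error by default
  (`variance_policy = "error"`); silently dropping genes would make
  pipeline outputs incomparable. `"drop"` removes them with a warning.

## Similarity: scope of the min–max normalisation

The inner-product variant rescales each entry of `S'S = S^T S` by the
minimum and maximum over *the union of its row and column* (2n entries,
diagonal included). Because `S'` is symmetric this scope is symmetric in
(i, j), so the normalised matrix is symmetric; symmetry is enforced
bitwise by mirroring the upper triangle. Two consequences are accepted
rather than patched:

* entries can be exactly 0 or 1 (at the scope extrema). Powering and TOM
  tolerate the endpoints, so they are kept, not clipped;
* with the diagonal in scope, an off-diagonal entry can only reach 1 when
  two gene profiles coincide, since `<a, b> <= max(|a|^2, |b|^2)`.

The diagonal itself is overwritten to 1 after normalisation (and TOM fixes
its own diagonal), so its value never influences degrees, overlaps or
clustering. The Pearson baseline applies the *same* row/column min–max
rescaling to the correlation matrix — not the conventional `(1 + r)/2` —
so that the baseline differs from the calibrated variants only in the
similarity statistic itself.

## Soft threshold: the signed fit index and the no-fit fallback

`scale_free_fit` bins the weighted degrees into `n_bins = 10` equal-width
bins, drops empty bins, and regresses `log10` frequency on `log10` mean
bin degree. Two details matter:

* **Selection uses the signed index** `-sign(slope) * R^2`. A power-law
  degree distribution requires frequencies that *decrease* with degree; a
  good linear fit with rising frequencies (common for dense similarity
  networks at low powers) must not count as scale-free. The raw `R^2` is
  still reported.
* **The no-fit case is expected, not exceptional.** Some data sets never
  meet the scale-free criterion at any power. The report is then flagged
  (`not_scale_free`) and the best signed fit is used — restricted to
  powers whose mean weighted degree stays above a connectivity floor
  (`min_mean_k = 3`), because an argmax taken over an essentially empty
  network (mean degree below one edge-weight per node) selects a power at
  which no structure survives. The floor only affects the fallback; the
  smallest-qualifying rule is unchanged.

Defaults: `beta_grid = 1:20`, `r2_cut = 0.85` — the community's customary
grid and cut; all three knobs are exposed in `pipeline_config()`.

## Topological overlap

`tom` implements `omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
with `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`,
i.e. the sums exclude the endpoints and the diagonal is held at zero
during computation (the alternative, including the diagonal, breaks the
`omega <= 1` bound). The matrix form uses one matrix product — the
excluded `u = i, j` terms vanish automatically because the diagonal is
zero — and the result is mirrored for exact symmetry. A verbatim
triple-loop oracle checks equality to 1e-10 on random networks up to
n = 30 in the tests.

## Dynamic tree cut

The reference shape-aware cutting procedure is implemented in-package on
top of `stats::hclust` average linkage:

* **Cut height is a fraction of the joining-height range** (5th percentile
  to maximum), default 0.99. On `1 - TOM` dissimilarities the whole tree
  can sit below any fixed absolute height, so an absolute static cut would
  silently return a single branch; the fractional reading matches the
  cited method's own default semantics.
* **Branch decomposition.** Below the cut, a merge is a module boundary
  when both sides hold at least `min_module_size` genes and at least one
  side is *distinct*: its internal joining height sits at least a minimum
  gap below the merge. `deep_split` (0–4, default 2) maps to that gap —
  `(4.5 - deep_split)/4.5 × 0.25` of the height range — and to a scatter
  ceiling (`0.64 + 0.08 × deep_split` of the range) below which a branch
  is emitted whole. Loose branches shed undersized side-branches to the
  unassigned pool and are descended further.
* **Core trimming.** An emitted branch may still carry hangers-on that
  merged inside it. Members whose average within-branch dissimilarity
  exceeds the boxplot fence (q75 + 1.5 IQR) by a meaningful margin
  (at least 0.02 on the [0, 1] dissimilarity scale, so microscopic spreads
  trim nothing) are returned to the pool.
* **Hybrid (PAM-like) assignment.** Each pooled gene joins the module with
  the smallest average dissimilarity to its members — but only if that
  average does not exceed the module's most peripheral member's, capped by
  `max_pam_dist` (default: the effective cut height). Without the
  periphery condition, TOM-based pipelines absorb unstructured background
  genes wholesale, because topological overlap makes every gene moderately
  similar to every hub.
* Ties in the hybrid stage break toward the lowest module index; labels
  are renumbered 1..k by decreasing size (ties by first member index), so
  the whole procedure is deterministic and permutation-equivariant.

`min_module_size = 30`, `cut_height = 0.99` and `deep_split = 2` are the
published defaults of the cited cutting method and are used for all four
pipelines alike.

## Enrichment and module quality

Hypergeometric tails are exact (`phyper`), never approximated, and
strictly positive, so `log10 p` is always defined. Design points:

* the universe defaults to *all* genes of the assignment, annotated or
  not, matching the common invocation of enrichment tools; a different
  universe can be passed explicitly;
* no multiple-testing correction is applied before selecting the five
  smallest p-values — the quality score ranks raw p-values by design;
* the five-smallest selection pools all six batteries (3 namespaces × 2
  directions) and treats (term, direction) pairs as the unit, with ties
  broken by term id then direction for determinism;
* a module with fewer than five testable results keeps them all, divides
  by their count, and is flagged `fewer_than_five`, rather than producing
  an undefined score.

## The synthetic benchmark

`synthetic_spec()` defines the standard benchmark: 1000 genes × 50
samples, five planted modules of 150 genes (250 background genes), within-
module correlation ρ = 0.7 via a per-module latent factor, per-gene
baselines uniform on [5, 15], Gaussian noise with sd 0.3, and an
annotation map with two planted terms per module (precision 0.9, recall
0.8) plus 30 random decoy terms across the three namespaces. The matrix
is shifted (never truncated) to strict positivity, so planted correlations
are untouched.

The noise scale deserves a word: the calibration's variance divisor makes
absolute dispersion meaningful, and sd 0.3 on the 5–15 baseline scale
gives per-gene total dispersion of about 0.55 — the regime of processed
log-scale expression data, where the method is designed to operate. At
dispersions far above 1 the logistic argument collapses and all
similarities crowd together; that regime is real but is not what the
benchmark emulates.

What the generator does **not** emulate: probe effects, batch effects,
heavy-tailed platform noise, overlapping or nested modules, and
correlated background. Passing the benchmark therefore shows that the
pipelines recover clean planted structure and that the enrichment
machinery ranks planted terms first; it does not certify performance on
real microarray data, where preprocessing choices (normalisation, probe
collapsing) precede everything this package sees.

On this benchmark (sizes as above; tests use 100 seeded annotation draws,
20 seeded pipeline comparisons, and oracle sweeps at n ≤ 30 for TOM and
N ≤ 60 for the hypergeometric) the gamma pipeline recovers the planted
partition essentially exactly, the planted term is the top
over-represented hit in ≥ 95% of draws, and gamma's average module
quality beats beta's in the large majority of seeded runs, with the
Pearson baseline behind both — the qualitative ordering the calibrated
workflow is meant to exhibit.

## Known limitations

* The degree distributions of dense calibrated-similarity networks rarely
  satisfy the scale-free criterion; the flagged fallback is then in
  charge, and results depend on the connectivity floor. The flag is
  surfaced in every report and should be inspected.
* The alpha pipeline (inner-product similarity) is sensitive to per-gene
  scale by construction; on benchmarks with many background genes it
  tends to leave large fractions unassigned. This is a property of the
  similarity, not a defect of the clustering.
* `dynamic_tree_cut` is this package's implementation of the shape-aware
  cutting idea, parameterised to behave like the published defaults; it
  is not a line-by-line port of the reference implementation, and module
  boundaries on borderline branches can differ from it.
* All stages hold dense n × n matrices in memory; n around 10⁴ genes is
  the practical ceiling on a laptop-class machine.
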