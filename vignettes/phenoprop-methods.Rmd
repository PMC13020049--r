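---
title: "Methods: network propagation for rare-disease phenotype comparison and gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation for rare-disease phenotype comparison and gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprop)
```

## The model

`phenoprop` studies rare monogenic disorders whose known gene lists are too
small and too disjoint to compare directly. Every analysis rests on one
primitive: the propagation profile of a trait, the stationary distribution
of a random walk with restart (personalized PageRank) over a weighted
undirected protein–protein interaction network,

$$x = d \, P^\top x + (1 - d)\, r,$$

where $P$ is the row-stochastic transition matrix (edge confidences as
transition weights by default), $r$ is uniform over the trait's seed genes
(each seed carries equal weight), and $d$ is the damping — the probability
of following an edge rather than restarting. The profile assigns a score to
*every* protein, measuring its network proximity to the trait's genes; two
disorders with disjoint gene lists can still have nearly identical
profiles if their genes occupy the same network neighborhood. That is the
assumption the whole package leans on: interacting proteins share cellular
roles, and their disruption produces similar phenotypes.

### Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `damping` | 0.85 | probability of following an edge; the convention of the standard PageRank implementations. Smaller values keep mass nearer the seeds, larger values diffuse further. |
| `weighted` | `TRUE` | edge confidences (in (0,1]) as transition weights; a flag disables this for sensitivity analysis. |
| `tol`, `max_iter` | 1e-12, 1000 | L1 residual convergence of the power iteration. |
| network `min_weight` | 0.4 | inclusive edge-confidence cut at load time (the usual STRING-style threshold). |
| evidence thresholds | > 0.5, ClinVar > 0.8 | strict per-source evidence-score cuts defining seed genes. |
| seed minima | human ≥ 2, mouse ≥ 10 | a human trait needs at least two genes to propagate meaningfully; the mouse minimum excludes models specific to a single monogenic disease. |
| Walktrap `max_size`, `max_rounds`, `steps` | 20, 5, 4 | protein complexes are expected to be small; modules above 20 genes are re-clustered up to 5 rounds; 4 is the cited Walktrap default walk length. |
| association `alpha` | 0.05 | BH-adjusted one-sided Wilcoxon threshold, plus the requirement of ≥ 1 trait seed gene in the module. |
| phenotype selection `k` | 20 / 10 | 20 nearest mouse phenotypes for joint clustering, 10 for gene prediction (the recovery optimum). |
| permutations | 1000 | random-seed permutations behind the propagation feature's empirical p-value. |
| training design | 5 genes/round, 150 negatives/round | disjoint 5-gene training sets per disease, pooled logistic fit. |
| evaluation design | 10 rounds, 1000 negatives | per test disease; PR AUC, partial AUROC (specificity 0.95–1.0), AUROC. |
| expression | ANOVA alpha 0.01, 10%/10% holdout | cell-type feature selection and train/test split. |
| GSEA | max size 2000, BH q < 0.05 | preranked enrichment of the final rankings, seeds excluded. |

## Numerical choices

**Solver.** The fixed point is computed by power iteration with L1 residual
below `tol`, nodes in lexicographic order, which makes runs bit-reproducible.
Profiles conserve mass (sum 1 to 1e-9). Mass reaching a degree-zero node is
teleported back to the restart distribution; under that convention the fixed
point is also the column-normalized solution of the sparse linear system
$(I - dP^\top)y = r$, exposed as `propagation_config(method = "linear")`.
One factorization then serves every restart vector, which is what makes
thousand-permutation nulls and multi-trait simulation studies cheap; the two
methods agree to ~1e-14 and the test suite asserts their equality against an
independent dense solve.

**Standardization.** Profiles are z-scored per trait across genes with the
sample-SD convention (R's `scale`), the same convention used for expression
rows. Euclidean distances between traits are taken on these z-scores.

**Rank-sum association.** A module is compared against the full network
*including itself*, which reads the association rule literally; this
guarantees ties, so the p-value uses the normal approximation with tie
correction (and continuity correction). The complement reference, which
admits exact p-values for small modules, is available by flag and is what
the exact-enumeration oracle tests exercise.

**Empirical p-values.** All permutation p-values use the add-one convention
$(1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$: never zero, valid under
BH, and uniform under the null. GSEA p-values are one-sided against the
same-sign portion of the permutation null (the classic convention); against
the full null the p-values of random sets concentrate below ~0.6 and can
never be calibrated.

**Ties and determinism.** Gene rankings break score ties lexicographically;
every stochastic routine takes an explicit integer seed and derives
per-stage substreams, so a fixed master seed reproduces a whole study.

**Geometric mean under zeros.** Propagation scores are strictly positive on
the component containing the seeds but can be zero on disconnected
components; aggregation floors scores at machine epsilon before the
log-mean, which preserves ordering without producing $-\infty$.

## The synthetic worlds

`generate_world` wires a planted-partition (stochastic block) graph:
`n_modules` blocks of `module_size` genes with intra-module edge probability
`p_in`, everything else at `p_out`, leftover genes as background. This is
the simplest graph family whose "modules" match what Walktrap is asked to
find, and it keeps the oracles analytic (intra-module edge counts are
binomial; ground-truth membership is exact). Human traits draw
`(1 - seed_noise_frac)` of their seeds from their assigned module(s) —
round-robin, one module per trait by default, two to emulate multi-systemic
disorders — and the rest uniformly elsewhere; mouse phenotypes likewise with
at least 10 seeds. Traits sharing a module share its organ label, which is
what makes phenotype-pair recovery testable against planted truth.
Expression matrices are baseline Normal(5, 1) truncated at zero, with the
disease-module genes shifted by `effect_size` (in baseline-SD units) in the
designated signal cell types.

Default study conditions: 400 genes, 8 modules of 20, `p_in` 0.3 / `p_out`
0.02, human seed counts uniform on 4–12 (explicit per-trait counts can be
given where a design needs exact seed-size strata, e.g. ≥ 20-seed training
diseases and ≥ 10-seed test diseases), mouse seed counts 10–16, 10% seed
noise. Simulation studies in the tests and the acceptance script use worlds
of 100–1000 genes; those sizes give every property comfortable signal while
keeping a full run in minutes on one CPU.

What the generator does *not* emulate: scale-free degree structure (a
background-hub parameter exists but is off by default, since no calibration
target is stated for the real network's degree bias), ontology structure
among mouse phenotypes, and correlated evidence sources. Passing tests on
these worlds therefore demonstrate the *machinery* — that each stage
recovers planted structure under its stated assumptions — not that the
biological databases satisfy those assumptions.

## Design decisions that were genuinely open

- **Duplicate edges** collapse to the maximum weight: conservative retention
  of the strongest evidence.
- **Seed permutations** sample uniformly over all network nodes, reading
  "random seed genes" literally; degree-matched sampling is available as an
  option for sensitivity analysis.
- **Aggregation across phenotypes** averages *scores* (geometric mean, then
  rank), not ranks, following the literal description; a seed-count baseline
  is provided because omitting propagation from the integration step is a
  known ablation.
- **Feature orientation**: permutation p-values and aggregate ranks are
  converted to "higher = better" (1 − p, 1 − rank/n) before min–max scaling,
  so positive logistic coefficients mean informative features.
- **Negative sampling** excludes only the disease's own seeds by default
  ("genes not associated with the respective disorder"); excluding other
  diseases' seeds too is a flag.
- **Partial AUROC** is McClish-standardized so chance = 0.5 and perfect = 1
  on the specificity 0.95–1.0 window; the raw area is available by flag.
- **BH scope** for module association is per trait (adjust across modules
  within each trait); joint adjustment is a flag.
- **Per-organ recovery negatives** include pairs sharing other phenotypes by
  default; a flag excludes them.

## Known limitations and honest caveats

- **Row-scaling couples cell types.** Z-scoring expression across cell types
  forces each gene's row to mean zero, so a +2 SD shift in 3 of 20 cell
  types necessarily induces a ≈ −0.24 SD group difference in the other 17.
  With enough positive genes the ANOVA detects this compensatory effect —
  correctly, since it is a true difference in relative expression. "Exactly
  the planted cell types selected" is therefore a majority outcome, not a
  certainty, and the validation asserts it as such; with high-powered
  positive sets the selection deliberately includes low-expression cell
  types, which is also how the expression features are meant to be read.
- **Hold-out evaluation at desk scale.** Held-out disease genes can never be
  mouse seeds while other genes can; in small worlds where mouse seeds cover
  a large gene fraction this depresses random-phenotype recovery below
  chance, and planted-module genes carry a degree advantage that inflates
  it. Both artifacts shrink with network size (seeds are ~1% of genes at
  database scale), so chance-level null checks are run on seed-sparse,
  equal-degree worlds.
- **Saturated score scales.** Logistic probabilities saturate near the top
  of a ranking; weighted-KS enrichment with exponent 1 then concentrates
  hit weight on a few genes and single lucky genes inflate null enrichment
  scores. The exponent is exposed; exponent 0 (unweighted, scale-invariant)
  is the robust choice for probability-scale rankings.
- The module "round" bookkeeping records a module that Walktrap declines to
  split (a single community) at the maximum round, since re-clustering it is
  a no-op — such modules simply do not continue to split.
- Gene identifiers are opaque case-sensitive strings: no ortholog mapping,
  no identifier conversion; inputs are expected to be pre-mapped.
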