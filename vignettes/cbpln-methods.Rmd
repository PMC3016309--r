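---
title: "Contextual process linkage networks: model, null models, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual process linkage networks: model, null models, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpln)
```

## The problem

Gene-set enrichment asks which individual processes respond in an experiment.
This package asks a different question: which *pairs* of processes talk to
each other through the interaction network in a given biological context?
Two processes can each look unremarkable in isolation while the interface
between them — physical and functional interactions connecting their member
genes — carries a concentrated transcriptional response. The output is a
*directed* network over processes: an edge A → B means that genes annotated
with B, sitting just outside A in the interaction network, respond strongly
and are strongly connected to responding genes inside A.

Three inputs are required, sharing one gene namespace:

1. a weighted undirected functional interaction network (e.g. STRING-style
   confidence-weighted associations, thresholded and rescaled into (0, 1]),
2. a gene set collection (e.g. MSigDB GMT files) defining the processes and
   the annotation universe `U` (all genes with at least one annotation),
3. a per-gene differential-expression p-value table for the contrast of
   interest (e.g. a limma contrast between two culture systems).

## The score

Each gene gets a perturbation score `s(g) = |log10 p(g)|`; genes without a
measured p-value score 0 (absence of evidence contributes nothing). For an
ordered pair (A, B), let `N(A)` be the genes adjacent to A's members but not
themselves annotated with A, and `N(A,B)` the subset annotated with B. The
contribution of A's neighborhood to a gene `v` is

```
f_A(v) = max over neighbors u of v with u in A of  w(u, v) * s(u)
```

— one high-confidence interaction with one strongly perturbed A-gene
suffices — and the contextual linkage score is

```
S(A, B) = sum over v in N(A,B) of  s(v) * f_A(v).
```

With all scores and weights equal to 1, `S(A,B) = |N(A,B)|`, the plain
interactor count of the context-free baseline (the hypergeometric
process-linkage test, also implemented, as `build_bpln()`); the contextual
score is its perturbation- and confidence-weighted generalization.

Because topology alone can inflate `S`, a background score `S_bg` is
computed by giving *every* gene the mean score of the measured genes in `U`;
the normalized statistic `S_norm = S − S_bg` (possibly negative) is what the
pipeline tests by default. The normalization is applied identically to every
null replicate: observed and null statistics are always the same functional
of the (randomized) data.

## Significance: two permutation null models

The weighted score has no tractable analytic null, so significance is
empirical, with R = 10,000 replicates by default:

* **Gene-set randomization** permutes the gene labels of the gene–annotation
  bipartite graph, which preserves every set size and every co-annotation
  count, and replaces the *target* set B by its randomized image (the source
  set and network stay fixed). Which side to randomize is genuinely
  ambiguous in the method's prose; randomizing B directly generalizes the
  context-free test, whose random variable is the annotation of A's
  neighbors with B. A `randomize_set = "source"` switch provides the other
  reading.
* **Network randomization** rewires the network by degree-preserving edge
  swaps (Q = 100 attempts per edge; Q is a convention — the method's printed
  value is not recoverable): each attempt picks two edges, proposes one of
  the two endpoint pairings at random, and applies it only if no self-loop
  or duplicate edge would result. Node degrees, the node set and the weight
  multiset are preserved exactly; each weight travels deterministically with
  its surviving edge slot.

The empirical link p-value is the fraction of null scores *strictly larger*
than the observed one, exactly as the method states it. The strict rule can
emit p = 0; a `(count + 1)/(R + 1)` pseudo-count estimator is available
behind `pseudocount = TRUE` for users who need p-values bounded away from
zero, but the default follows the stated rule.

Each test's p-values are adjusted with the Benjamini–Hochberg step-up
(monotone by construction in the raw-p ordering, capped at 1) across the
family of evaluated pairs, and a link enters the final directed graph only
if its adjusted p-value is at or below `fdr_alpha` under *every* configured
test.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `permutations` (R) | 10,000 | null replicates per test |
| `swap_multiplier` (Q) | 100 | swap attempts per edge, per replicate |
| `fdr_alpha` | 0.01 | cutoff on BH-adjusted link p-values |
| `min_interactors` (K) | 10 | minimum `abs(N(A,B))` for a pair to be evaluated |
| `log_base` | 10 | base of the perturbation log-score |
| `weight_min`, `weight_scale` | 500, 1000 | raw-confidence threshold and rescaling divisor |
| `normalize` | TRUE | test `S − S_bg` rather than `S` |
| `seed` | — | master seed; all streams derive from it |

The K ≥ 10 filter is applied *before* testing and defines the BH family:
pairs with few exclusive interactors yield unstable permutation p-values and
would otherwise consume the FDR budget. The log base only rescales all
scores jointly; empirical p-values are invariant to it (this invariance is
asserted exactly in the acceptance tests), so it affects reported score
magnitudes, not inference. The weight rescaling by 1/1000 maps STRING-style
confidences (150–1000) into (0, 1], which bounds each edge's contribution
and makes the unit-weight reduction meaningful; whether the original method
rescaled weights is not stated, so the divisor is exposed in the
configuration.

## Numerical and algorithmic choices

* **Hypergeometric population.** The context-free baseline p-value draws
  from `U \ G_A` (members of `N(A)` can never be A-annotated, so the
  sampling frame excludes A too). Note a subtlety: the bipartite label
  permutation samples the randomized target set from *all* of `U`, so the
  exact law of the gene-set-randomization statistic under unit
  scores/weights is hypergeometric with population `U`, not `U \ G_A`. Both
  conventions are internally consistent and documented; the package keeps
  the `U \ G_A` convention for `bpln_link_pvalue()` and validates the
  empirical test against the population-`U` law it actually samples.
* **Averaging set for `S_bg`.** The mean is taken over genes of `U` with a
  measured p-value. Averaging over all genes would drag the background
  toward zero through unmeasured genes that carry no evidence either way.
* **Shared null replicates.** By default one randomized annotation (or
  network) per replicate is scored against *all* ordered pairs
  (`share_null = TRUE`). Per-pair marginal distributions are identical to
  independent streams; only the (unused) cross-pair joint distribution
  differs. Independent per-pair streams are available but cost a full
  randomization per pair per replicate — at R = 10,000 and a hundred pairs
  that is a million edge-swap randomizations, which is why sharing is the
  default.
* **Determinism.** Sub-seeds derive deterministically from the master seed
  and a context key (test name, replicate index, pair), so results do not
  depend on evaluation order, and identical inputs + seed give byte-identical
  link tables.
* **Degenerate inputs.** Empty neighborhoods score 0 and get p-value 1 from
  the baseline; a network with no swappable edge pair (a path, a complete
  graph) yields a degenerate network null concentrated at the observed
  score, hence p = 0 under the strict rule — flagged by the all-tie pattern
  and avoidable with the pseudo-count estimator. Zero expression p-values
  are floored at `1e-300` before the logarithm.
* **Ties.** The strict "larger than" rule ignores ties between observed and
  null scores, which makes the test slightly anti-conservative in discrete
  settings (unit scores); with continuous weights and p-values ties occur
  only structurally (identical term multisets).

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds a complete input triple with known ground truth:
~500 genes, 8 processes of 25–40 genes, background interactions at
probability 0.01 with weights uniform on (0.5, 1], and 5 planted links —
dense cross-set blocks (cross-edge probability 0.3, weights on (0.8, 1])
between the exclusive parts of two processes, whose incident genes receive
expression p-values uniform on (0, 0.001) while all other genes draw
uniform (0, 1) p-values. Planted interactions are undirected and perturb
both endpoint sets, so each planted link is genuinely bidirectional; the
truth records both orientations.

Process memberships are a *partition* by default (`overlap_frac = 0`,
configurable up to 0.5). This is deliberate: if a gene shared between an
uninvolved process C and a planted partner B sits inside the planted block,
C acquires a genuine, strong link to the other planted endpoint — correct
inference, but a corrupted benchmark, because the truth table would count it
as a false positive. A planted-truth benchmark must keep its truth exact;
users wanting overlapping sets can raise `overlap_frac` and interpret
"false" positives accordingly.

The generator does not emulate STRING's evidence-channel structure, MSigDB's
hierarchical redundancy between collections, probe-level microarray noise,
or correlated differential expression within pathways. A green planted-link
test therefore establishes that the pipeline detects concentrated,
high-confidence, perturbation-aligned cross-set structure against a sparse
background at the stated effect sizes — not that it reproduces any
database-dependent result on real data.

## Validation summary

The test suite asserts, among others: the exact reduction `S = |N(A,B)|`
under unit inputs; agreement of the hypergeometric tail with exhaustive
enumeration for every instance with population ≤ 12; convergence of the
empirical gene-set p-value to its analytic law within Monte-Carlo error;
type-I calibration of both tests on a pure null fixture; recovery of all or
nearly all planted links at FDR 0.01 with zero false calls across seeds;
exact invariance of empirical p-values under rescaling of scores or weights;
exact structure preservation by both randomizers; agreement of the BH
adjustment with a brute-force step-up; and a constructed asymmetric world in
which A → B is called while B → A is not (the reverse pair has too few
exclusive interactors to be evaluated) — links are directed end to end.
Stochastic checks run at R = 1,000 (calibration, recovery) or R = 10,000
(convergence), with fixed seeds chosen before the outcomes were observed.

## Known limitations

* Empirical p-values are bounded below by 1/R; deep tails require larger R
  or the pseudo-count estimator, not extrapolation.
* The network null conditions on the degree sequence only; richer structure
  (clustering, weight–degree correlation) is not preserved, and on very
  small or dense graphs few swaps are feasible, degenerating the null.
* Scores are unsigned: up- and down-regulation are not distinguished, and
  alternative neighbor aggregations (e.g. sums instead of the maximum) are
  out of scope.
* One perturbation table per run: multi-contrast designs are separate runs
  of the same pipeline.
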