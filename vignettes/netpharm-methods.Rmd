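---
title: "netpharm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netpharm: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

This vignette documents the statistical models behind each pipeline stage,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the methodology left them open.

## Bioavailability screening

The Abbott bioavailability score is a rule-table estimate of the
probability that a compound achieves more than 10% oral bioavailability.
Our implementation branches on the predominant charge state near pH 7:
anionic compounds are scored by topological polar surface area (TPSA in
Å²: > 150 → 0.11, (75, 150] → 0.56, ≤ 75 → 0.85), all others by
rule-of-five compliance (at most one violation among MW ≤ 500 g/mol,
logP ≤ 5, H-bond donors ≤ 5, acceptors ≤ 10 → 0.55, otherwise 0.17).
The screen keeps compounds with `bs_min = 0.10`.

A consequence worth stating plainly: the smallest constant in the rule
table is 0.11, so a 0.10 cutoff cannot by itself remove any compound whose
score came from this table. The cutoff still matters when scores are
supplied externally (the `bs` input column mirrors workflows where an ADME
web service provides them), and `bs_min` is configuration, not a constant.

## Similarity-ensemble target prediction

A target set $A$ is a protein with $N_A$ known ligand fingerprints. For a
query fingerprint $q$,

$$\mathrm{raw}(q, A) \;=\; \sum_{\ell \in A} T_c(q,\ell)\,
  \mathbf 1\!\left[T_c(q,\ell) > t\right], \qquad t = 0.45,$$

with $T_c$ the Tanimoto coefficient. The threshold comparison is strict
(`>`), and raw scores are normalized by $N_A$ for reporting. Specificity is
judged against a random-background model:

$$Z_A \;=\; \frac{\mathrm{raw}(q,A) - \mu N_A}{\sigma\, N_A^{\lambda}},
  \qquad \lambda = 0.335 .$$

The numerator centers the raw score at its background expectation (which
grows linearly in set size); the denominator is the empirical power law by
which background noise grows with set size — sub-$\sqrt N$ because
thresholded contributions are sparse and positively dependent.

**Background calibration.** `calibrate_background()` draws random
(query, ligand-set) pairs with the query sampled *from the pooled database
ligands* and the set a random subset excluding the query. This is
deliberate: $\mu$ and $\sigma$ describe chance resemblance *within the
database*, and a database of mutually similar ligand families has far more
chance similarity than unrelated random bit vectors would suggest. Fresh
random vectors at matched density essentially never clear $t = 0.45$ at
realistic fingerprint lengths, which would leave the model degenerate (the
function errors rather than returning a meaningless fit). $\mu$ is the
origin-constrained least-squares slope of mean raw score on $N$; $\sigma$
comes from a log–log fit of SD(raw) on $N$ with $\lambda$ held fixed,
using only sizes with nonzero SD, and a single size degenerates cleanly to
a one-point fit.

**Acceptance cutoff.** `z_min` defaults to 3.0 — roughly "three background
SDs" — but the methodology this package operationalizes states no cutoff,
so it is exposed as configuration and the recovery tests use
`z_min = -Inf` with rank-based criteria instead.

**Ties.** Predictions sort by $Z$ descending, then normalized score, then
target id, so output order is deterministic.

**Fingerprints.** The statistics operate on plain 0/1 vectors; nothing in
the pipeline requires a chemistry engine. For real structures,
`fingerprint_from_smiles()` canonicalizes with Open Babel and applies an
order-invariant Morgan-style circular hash (radius 2, 2048 bits; atom
invariants: element, heavy degree, total bond order, formal charge). Any
SMILES spelling of a molecule maps to the same fingerprint because hashing
happens on the canonical graph with sorted neighbor contributions.

## Differential expression

Expression values are log2 intensities; the reader applies
$\log_2(x + 1)$ with a warning when a matrix's maximum exceeds 50, a
heuristic that separates logged (≈ 2–16) from unlogged (thousands)
microarray scales. The log fold change is mean(case) − mean(control), so
positive = up-regulated in disease.

The default test is an empirical-Bayes **moderated t**: per-probe pooled
variances $s^2$ (df $d = n_1 + n_2 - 2$) are shrunk toward a prior,
$s^2_{\mathrm{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and
$t = \mathrm{logFC} / (s_{\mathrm{post}}\sqrt{1/n_1 + 1/n_2})$ is referred
to $d_0 + d$ df. The prior $(d_0, s_0^2)$ is estimated by moment matching
on the log sample variances: with $e = \log s^2 - \psi(d/2) + \log(d/2)$,
the excess of $\mathrm{var}(e)$ over $\psi'(d/2)$ identifies $d_0$ through
the trigamma inverse, and $s_0^2$ follows from the mean. When the observed
spread does not exceed the sampling expectation, $d_0 = \infty$ and all
probes share $s_0^2$. Setting `d0_override = 0` disables shrinkage; the
statistic then *is* the ordinary pooled-variance t (not Welch — the two
coincide only for equal group sizes and equal variances), and the test
suite verifies that limit against `t.test(var.equal = TRUE)` and the full
estimator against the reference empirical-Bayes implementation.

A **Welch t** with Satterthwaite df is available for users who prefer not
to assume equal group variances. Zero-variance probes get the degenerate
limit (p = 0 for unequal means, 1 otherwise) and a `degenerate` flag
rather than NaN.

The screening filter is $|\mathrm{logFC}| \ge 0.5$ and $p \le 0.05$, both
inclusive, on **unadjusted** p-values — this mirrors the common GEO
re-analysis convention for exploratory target discovery, and the boundary
inclusivity follows the stated criterion exactly. Probe → gene collapsing
keeps the probe with maximal $|\mathrm{logFC}|$ (a "most responsive probe"
rule; `how = "mean"` averages instead, combining p as the minimum).
Because the filter precedes collapsing, both probe-level and gene-level
counts are reported.

## Networks

Key targets are the exact intersection of predicted target genes with the
disease set (DEG union ∪ disease-gene lists), after upper-case symbol
normalization. The compound–target network has one unweighted edge per
retained prediction; betweenness is computed on the unweighted graph
(shortest-path counting with endpoints excluded, each unordered pair once)
and reported both raw and normalized by $(n-1)(n-2)/2$, since conventions
differ between tools. PPI edges keep their combined score (0–1000) as an
attribute — the default cutoff 400 is the usual "medium confidence" — but
scores never enter path computations. The "disease core" hub rule is
operational: key targets that are also in the expression-derived DEG
union, ranked by degree with betweenness then id as tie-breaks.

## Enrichment

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, evaluated through
the stable log-scale machinery of `phyper`. The universe defaults to all
genes appearing in the annotation collection — the conservative choice
when the collection is the only gene inventory available — and can be
overridden. Adjustment is Benjamini–Hochberg across all terms with at
least one query hit; significance is $p_{\mathrm{adj}} \le 0.01$ by
default, with a `strict` flag for `<` because both conventions appear in
practice. Only over-representation is tested (one-sided).

## The synthetic generator

The generator emulates the *statistical structure* the pipeline assumes,
with ground truth recorded for every planted signal:

- **Ligand universe:** each target's ligands are independent perturbations
  of a per-target seed bit vector, with the flip probability solved
  numerically so the expected within-set Tanimoto equals the requested
  level; across targets, ligands are independent. Default bit density 0.3,
  length 512.
- **Query compounds:** actives are ligand copies with a fixed number of
  bit flips; decoys are fresh random vectors at the universe's density.
- **Expression:** per-gene baselines from Normal(8, 2) in log2 units
  (typical microarray scale), Normal(0, σ) noise, planted genes shifted by
  ±effect in cases only, with alternating signs so both volcano branches
  occur; ~30% of genes carry a second probe.
- **Annotations:** random gene sets plus one term exactly equal to the
  planted gene set. **PPI:** Erdős–Rényi edges with uniform scores.

What it does **not** emulate: real chemistry (fingerprint bits are
exchangeable, unlike substructure keys), correlated genes, batch effects,
array normalization artifacts, scale-free PPI topology, or nested GO
structure. Passing recovery tests therefore demonstrates that the
pipeline's inference machinery is correct under its own model assumptions,
not that the biological conclusions of any particular study are right.

The demo study (`make_demo()`) uses 30 targets × 8 ligands, 25 actives +
10 decoys, 2000 genes with 20 + 20 samples per chip and ~60 planted DEGs
(including every truly targeted gene, so the key-target intersection is
recoverable), 120 annotation terms, and runs in a few seconds. The
calibration checks use 5000 genes (null type-I), 100 planted genes at
effect 2.0 and σ 0.5 (sensitivity), and 5000 background samples
(μ recovery) — sizes at which the binomial/Monte-Carlo error of each
estimate is comfortably below the tolerance being checked.

## Degenerate inputs and numerical notes

- Tanimoto of two all-zero vectors is defined as 0.
- `raw_score` on an empty ligand set, a background with no similarity
  above threshold, an empty enrichment universe, and group sizes below 2
  are all errors, not silent NaNs.
- All generators are deterministic functions of their seed; the pipeline
  report omits timings so reruns are byte-identical.
- Symbol matching is upper-case throughout; duplicate and self-loop edges
  are removed on graph construction.

## Known limitations

- The moderated-t prior assumes a scaled inverse-chi-square variance
  distribution; heavy-tailed variance outliers are not robustified.
- The bioavailability rule table covers the anionic/neutral dichotomy
  only; zwitterions and cations are treated as neutral.
- Set-vs-set prediction (multi-ligand queries) is supported by the scoring
  machinery but the pipeline queries single compounds.
- Enrichment treats terms as flat sets; no term-graph redundancy pruning.
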