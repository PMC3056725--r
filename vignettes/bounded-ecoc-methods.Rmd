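---
title: "Bounded gene selection for output-coded multiclass expression classifiers"
author: "sparseECOC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded gene selection for output-coded multiclass classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiclass classification of expression profiles lives in the regime
p ≫ q: thousands of genes, dozens of samples, M ≥ 3 phenotype classes.
Binary-mediated designs reduce the M-class problem to n binary tasks
through an M × n binary code matrix — One-Against-All (OAA, n = M) or a
general error-correcting output code (ECOC) — and each binary task
performs its own gene selection. Without a principled cap on how many
genes a binary classifier may use, selection either explores an enormous
search space or returns gene sets too large to support statistically
meaningful findings.

## The information budget

`sparseECOC` is built around a closed-form budget. Treat genes as i.i.d.
binary random variables, expressed with probability f, so one gene
carries at most the binary entropy H(f) = −f log2 f − (1−f) log2(1−f)
bits. The class label carries at most log2 M bits, and under information
equipartition across n independent binary classifiers each classifier
sees log2(M)/n bits. A classifier selecting a fraction Q of the p genes
therefore obeys

Q · p · H(f) ≤ log2(M) / n.

The ergodic estimate f = 1/p (the fraction of genes expressed in one
sample estimates the expression probability; complementing keeps it
below 1/2, where H is increasing) yields the operational cap

Q_max = log2(M) / (p · n · H(1/p)),  g_max = max(1, ⌊p · Q_max⌋).

`qMax()`, `geneCap()` and `geneBudget()` implement these; `binaryEntropy()`
exposes H; `fanoLowerBound()` gives the companion Fano bound on the
error probability; general f is available for sensitivity analysis via
the `f` argument. Note the cap uses exact `log2(M)`, not `⌈log2 M⌉`:
the ceiling appears only in code-capacity arithmetic (a code must
protect k = ⌈log2 M⌉ information bits); inside the budget it would be a
needless coarsening, and only the final gene count is floored. Q_max
decays as 1/n — the budget is a hyperbola in n — so larger output codes
force sparser binary classifiers, which is the design lever the whole
method rests on.

## Codes and decoding

`oaaCode(M)` is the identity code. LDPC codes are built from sparse
random bipartite (Tanner) graphs (`buildLdpcGraph()`): n message nodes
carry codeword coordinates, m = n − k check nodes demand even parity
over their neighbourhoods, and codewords are the GF(2) null space of the
parity matrix. Construction choices, all seeded and deterministic:

* near-regular column degree, target j = 3 (reduced to m − 1 for small
  m; for m = 2 column patterns mix degrees 1 and 2, since an
  all-even-degree parity matrix is structurally rank-deficient);
* duplicate edges are never accepted; 4-cycles are avoided for a
  bounded number of attempts, then tolerated (unavoidable in dense toy
  graphs);
* dependent check rows are resampled until the parity matrix reaches
  full row rank m, so exactly k = n − m information bits are protected;
* graphs whose code forces a coordinate constant are rejected — such a
  column would define a binary task with a single class, which no
  classifier can learn.

`enumerateCodebook()` maps the M classes onto M distinct codewords,
starting from messages 0..M−1 in natural binary order and resampling the
assignment (bounded, seeded) when the chosen rows leave a column
constant. The class-to-message mapping is not canonical; natural order
with resampling keeps it reproducible.

Decoding is soft. Bits map to channel symbols (−1)^b (0 → +1, 1 → −1,
fixed project-wide). Binary-classifier margins are standardized to unit
variance on training data, treated as outputs of an AWGN channel with
σ = 1 (the channel is a modelling device, so the scale is a convention;
standardizing the margins makes it consistent across columns), and
converted to log-likelihood ratios 2r/σ². `softDecode()` then runs
exactly one full sum-product round on the Tanner graph — p ≫ q limits
the diversity of the binary classifiers, and a single iteration avoids
overconfident message recirculation — and returns the class whose
±1-mapped codeword best correlates with the posterior LLRs (bit
posteriors after one round need not form a codeword, so the class
decision, not the bit decisions, is what is returned; ties break to the
lowest class index). With zero iterations this reduces to
nearest-codeword decoding. OAA models use hinge-loss decoding
(`hingeDecode()`): argmin over classes of Σ_j max(0, 1 − (2b−1)·margin).

## Gene ranking and the Q grid

Per binary task, genes are scored by the signal-to-noise ratio
S2N = (μ+ − μ−)/(σ+ + σ−) with population (divide-by-n) standard
deviations and an epsilon of 1e-9 in the denominator; the n vs n−1
convention is immaterial to the induced ranking but is fixed for
reproducibility, and the epsilon only matters for genes constant within
both classes. The g most important genes are the first g/2 and last g/2
of the ranking (two-ended selection: strongly negative scores are as
discriminative as strongly positive ones). Ranking ties keep the input
gene order, making selections deterministic.

The gene-fraction dimension is explored on a multi-scale grid
(`buildQGrid()`): anchors 0.001, 0.01, 0.1, 1; the first two logarithmic
segments split into 10 linear parts, the last into 100 — 121 fractions
in all — then truncated at the budget cap. Each fraction maps to an even
gene count g = 2·round(Q·p/2), deduplicated and kept within
⌊Q_cap·p⌋; the grid emits only even g so the two-ended rule never faces
a split tie. Whether the fraction-to-count mapping rounds or floors is
a free choice; rounding to the nearest even count is used throughout.

## The selection-bias-free protocol

Performance is estimated over stratified Monte Carlo 4:1 train/test
partitions (`montecarloPartitions()`; stratification keeps small classes
represented, and an exact `trainSize` mode covers conventions such as
45/15 on 60 samples). Within each training part only:

1. `selectNQ()` minimizes a stratified 10-fold CV error over
   [n_min, n_max] × (0, Q_max] at C = 1, where
   n_min = ⌈log2 M⌉ + 2, n_max = ⌈η log2 M⌉ (η ∈ {5, 10, 15});
   ⌈15 log2 M⌉ + 1 is excluded (a parity-only size that detects but
   cannot correct errors). OAA preselects n = M. Ties take the largest
   n — equivalently the sparsest per-classifier budget — then the
   smallest Q. One seeded LDPC graph per n is shared across the inner
   grid, isolating the (n, Q) comparison from graph resampling noise.
2. `optimizeC()` runs a factor-2 ladder from C = 1 in both directions,
   stopping each direction after three consecutive non-improvements;
   ties prefer C closest to 1, then smaller C. Joint (n, Q, C)
   optimization is deliberately avoided as prohibitively expensive.
3. `fitFinal()` rebuilds the selected code, reselects genes per column
   on the full training part, and fits linear SVMs (e1071, linear
   kernel, cost C) on features standardized with training statistics.

The held-out part is touched exactly once, by `predict()`. The inner CV
refits the S2N ranking inside every fold, so selection never sees
held-out samples at any level.

## Evaluation machinery

Per-partition metrics are test error, overall selected-gene count and
selection stability: all pairwise Salton cosine coefficients
|A∩B|/√(|A||B|) between per-partition gene sets (`meanStability()`;
200 partitions give 19 900 pairs). An empty gene set is an error, not a
zero — it signals an upstream bug.

Family comparisons use first-order stochastic dominance
(`dominanceAnalysis()`): Shapiro–Wilk normality p-values are reported
(they motivate the nonparametric route but never switch the analysis to
t-tests), then a two-sided and the two one-sided Kolmogorov–Smirnov
tests on the pooled ECDFs, with one-sided Mann–Whitney p-values for
concordance. F dominates G when the two-sided test rejects and only the
one-sided test against the F-favourable direction rejects; both or
neither rejecting is ambiguous. KS p-values use the asymptotic
Kolmogorov series (two-sided) and exp(−2·n_e·D²) (one-sided,
n_e = uv/(u+v)); the series is summed to convergence rather than
truncated at a fixed tolerance, so p-values can differ from `ks.test`'s
C implementation by up to ~3e-5 near t = 1 (in the package's favour).
Ties in the Mann–Whitney test use midranks with the tie-corrected
normal approximation. No multiple-testing correction is applied across
metrics.

## Synthetic data: what it does and does not emulate

`generateGaussianDataset()` plants class-exclusive markers —
`markersPerClass` genes per class, mean-shifted by `effectSize` noise-sd
units in that class only — on an i.i.d. Normal(0, σ²) background.
Class-exclusive markers make ground-truth recall unambiguous. Defaults
(M = 4, p = 1000, q = 100, 10 markers/class, effect 2σ, uniform class
proportions) are the package's reference recovery conditions: a
moderate effect at a realistic sample count, deliberately not a
separable toy. `generateBooleanDataset()` draws i.i.d. Bernoulli(f) gene
states and exists to validate the bound's ergodicity narrative (the
per-sample expressed fraction concentrates on f; plug-in per-gene
entropies approach H(f)), not to feed classifiers — SVMs and S2N operate
on real values, so the Gaussian model backs all classifier tests.

Neither generator emulates platform artifacts: probe effects,
normalization, batch structure, correlated co-expression modules, or
heavy-tailed noise. Passing tests therefore demonstrate the machinery
and its contracts under the stated statistical assumptions, not
performance on any real microarray or single-cell dataset.

## Numerical and scale choices

* GF(2) elimination, the null-space basis, and all decoding are exact
  integer/double arithmetic; tanh magnitudes are clamped at ±(1−1e−15)
  inside the check update to avoid infinite atanh.
* Degenerate inputs: zero-variance genes fall back to scale 1 during
  standardization; constant samples give NA Shapiro–Wilk p-values
  (reported, not fatal); infeasible (n, Q) grids raise errors that
  `runExperiment()` records per partition without aborting the run.
* Test and acceptance runs use 20 Monte Carlo partitions and a reduced
  four-point Q grid (0.004, 0.01, 0.02, 0.04) on the reference
  conditions above; these sizes exercise every stage of the protocol
  while keeping a full run in the minutes range on one CPU. The
  protocol-scale defaults (200 partitions, the full 121-point grid)
  are the function defaults.

## Known limitations

* Single-iteration sum-product only; no multi-iteration schedules,
  irregular degree optimization, or non-AWGN channels.
* Univariate S2N selection only; multivariate selectors (e.g. SVM-RFE)
  are out of scope.
* The expression probability f is never estimated from data; 1/p is a
  modelling choice inherited from the ergodic argument, and the bound
  is only as good as the independence assumptions behind it.
* LDPC codebooks for very small m are dense rather than sparse; the
  "low-density" character is only meaningful for larger n.
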