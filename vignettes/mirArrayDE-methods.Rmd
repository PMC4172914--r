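---
title: "Methods: miRNA array CT analysis with mirArrayDE"
author: "mirArrayDE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA array CT analysis with mirArrayDE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirArrayDE)
```

# Scope and data model

mirArrayDE analyzes miRNA profiling experiments run on TaqMan-style
low-density qPCR arrays: a few hundred fixed assays, cycle-threshold (CT)
readout, a handful of endogenous small-RNA control assays, and very small
group sizes (the motivating design is three newborn versus three adult rat
cochlear sensory epithelia on a 365-assay rodent panel normalized to the
snRNAs U44 and U48). The raw object is a `CtPanel`, a
`SummarizedExperiment` whose single assay holds CT values, whose `colData`
carries the two-group design, and whose `rowData` flags the control
assays. CT is on the cycle scale: one cycle equals one doubling, so one
cycle is one log2 unit of expression, and *lower* CT means *higher*
abundance.

# Normalization and fold change

`deltaCt()` subtracts, within each sample, the arithmetic mean of that
sample's finite control CTs from every feature CT. Averaging control CTs
is the geometric mean of control expression on the natural scale, the
standard multi-reference choice. This makes the result invariant to
per-sample shifts (input amount, overall efficiency): adding a constant
to all CTs of one sample changes nothing downstream. A sample whose
controls are all undetected cannot be normalized and is a hard error
naming the sample.

`foldChanges()` computes, per feature,

> ddCT = mean dCT(comparison) - mean dCT(reference),  FC = 2^-ddCT.

Group means of per-sample dCT are used (not per-sample pairing): the
groups are independent animals, so there is no natural pairing. With the
reference group first ("newborn") and comparison second ("adult"), FC > 1
means higher expression in the adult group. Swapping the groups maps FC
to 1/FC exactly, and log2(FC) = -ddCT to machine precision.

Undetected ("Undetermined") wells are missing values. The policy,
implemented in `filterDetected()`: a feature missing in more than half of
either group is removed and reported; otherwise group means use the
available wells. The default threshold of 0.5 keeps every group mean
supported by at least two animals at n = 3.

# The random variance model t-test

With three samples per group an ordinary t-test has four degrees of
freedom and almost no power. The random variance model (RVM; Wright &
Simon 2003, Bioinformatics 19:2448) assumes the per-feature true
variances are exchangeable draws from an inverse-gamma prior,

> 1/sigma^2 ~ Gamma(shape a, scale b),

under which an observed pooled residual variance s^2 on m degrees of
freedom satisfies s^2 · a · b ~ F(m, 2a) marginally. `fitRvm()` maximizes
exactly this marginal likelihood over (log a, log b) (Nelder-Mead,
relative tolerance 1e-10, at most 2000 iterations) from three starts
a0 in {1.5, 3, 10} with b0 = 1/(mean(s^2)(a0 - 1)), which matches the
prior mean variance 1/(b(a-1)) to the sample mean; the best of the three
is kept and the convergence flag is reported honestly. Features with zero
or missing variance are excluded from the fit; fewer than ten usable
features is an error rather than a silent bad fit. If the optimizer does
not converge, `rvmTest()` falls back to the ordinary pooled t-test with a
warning.

The moderated statistic per feature shrinks the pooled variance toward
the prior,

> s~^2 = (m s^2 + 2/b) / (m + 2a),   t = (mean1 - mean2) / sqrt(s~^2 (1/n1 + 1/n2)),

referred two-sided to a t distribution on m + 2a degrees of freedom. The
2a extra degrees of freedom are what the prior buys: at the study design
(m = 4) a fitted a near 2 roughly doubles the effective df. The test runs
on the dCT scale, where replicate values are approximately normal; fold
changes are attached afterwards. Two limits pin the implementation down
and are tested: as the prior vanishes (a -> 0, b -> infinity) the
statistic reduces to the ordinary pooled t, and as a -> infinity with
a·b fixed every variance is pinned at the prior mean, giving an
equal-variance z-like statistic.

Multiple testing across features uses Benjamini-Hochberg (`bhAdjust`,
delegating to `stats::p.adjust` after validating the inputs). The source
study names FDR control but not the procedure; BH is the standard,
reproducible choice, and it is kept strictly separate from the
enrichment stage's own empirical FDR below. `selectDifferential()`
applies p < `pThreshold` (default 0.05; the study does not print its
threshold) and a symmetric fold-change filter (default 2; FC >= 2 or
<= 0.5), then classifies direction: up iff FC > 1, down iff FC < 1, and
FC exactly 1 is never differential regardless of p — the published table
contains no such tie, so the rule only guards the degenerate case.

# Over-representation analysis

The array measures miRNAs, not mRNAs, so "differential genes" for
enrichment are defined as the union of predicted target genes of the
differential miRNAs (the target map is a two-column miRNA-to-gene table;
in practice a sequence-based target database, in testing the synthetic
generator). Up- and down-regulated miRNA sets are analyzed separately.
For a term containing n genes of a universe of N, of which Nf are
differential targets and nf fall in the term:

* `fisherEnrichment` — one-sided Fisher exact p, the hypergeometric
  upper tail P(X >= nf);
* `chi2Enrichment` — Pearson chi-square (1 df) on the 2x2 table,
  *without* Yates continuity correction: the correction would
  systematically raise the chi-square p and inflate the Nk count below,
  so plain Pearson is the conservative reading. Zero expected counts
  make the test undefined; such rows report p = 1 with a flag;
* `enrichmentRatio` — Re = (nf/n)/(Nf/N), the in-term proportion over
  the background proportion;
* `empiricalFdr` — FDR = 1 - Nk/T with Nk = #{terms: p_fisher < p_chi2}
  (strictly; ties count as failures, the literal reading of "less
  than") and T the number of terms tested in the run.

This FDR is a single scalar per run, not a per-term quantity — that is
what the defining formula yields — and the significance flag of every
term is `p_fisher < pThreshold` AND `run FDR < fdrThreshold`. BH
q-values on the Fisher p's are emitted alongside for reference but never
drive the flag. Defaults are the GO thresholds p < 0.001 and FDR < 0.05;
pathway runs conventionally relax to p < 0.05. Terms are size-filtered
to 3..500 genes after intersection with the universe — standard guards
against unstable tiny sets and uninformative giant ones. The universe
defaults to all genes appearing in the annotation collection; it is an
explicit argument because the "right" universe (array-represented
targets versus genome) is a judgment call.

# Bipartite networks and hubs

`mirnaGeneNetwork()` connects each differential miRNA to its predicted
targets; the adjacency weight of edge (m, g) is |log2 FC(m)|, so up- and
down-regulated miRNAs contribute on a common positive scale (direction
is a node attribute, as in the conventional red/blue rendering of such
networks). Gene nodes carry no weight of their own — the assay measures
no mRNA. `mirnaGoNetwork()` connects a miRNA to a significant term iff
they share at least one gene (a target of the miRNA annotated to the
term); its edge weight is the shared-gene count scaled by |log2 FC|.
`rankHubs()` orders nodes by unweighted degree — the number of partners,
the "contribution to the nodes around" — with lexicographic
tie-breaking for determinism; weighted degree is carried along for
reference. The handshake identity (left degrees, right degrees and edge
count all agree) is enforced by construction and property-tested.

# The synthetic generator

No raw CT data are available for the motivating study, so the package
ships a generator (`simulateCtPanel`, `simulateAnnotations`,
`simulateStudy`) whose defaults are the study conditions: 365 assays
plus U44/U48, 3 + 3 samples, 16 planted up-regulated features with log2
effects uniform on [log2 17, log2 602] and 2 down with effects on
[-log2 28, -log2 14] (bracketing the two published down-regulated fold
changes), feature baselines uniform on 18-35 CT, and per-feature
variances from the inverse-gamma prior with a = 2, b = 1 — a prior mean
variance of one cycle^2, i.e. about one cycle of replicate SD, a
realistic biological spread for small-RNA arrays, and deliberately the
same family the RVM test assumes so that calibration and
parameter-recovery tests are well posed. CT values are normal around the
feature mean, capped at cycle 40 (the instrument's last cycle); with
probability `undetectedCtProb` (default 0) a well is recorded as missing
("Undetermined"). Planted effects shift the second group's mean CT by
minus the log2 effect; controls never shift and carry a small fixed
technical SD (0.1 cycles) rather than a biological-prior draw —
endogenous controls are chosen precisely for stability, and a noisy
shared normalizer would inject a common per-sample shift into every
feature, corrupting both the scaled-F law of the sample variances and
per-feature test calibration.

The annotation generator gives every miRNA a Poisson-sized random target
set (mean 30 genes of a 2000-gene universe) and builds gene sets of
10-100 genes; planted terms sample their members with weight
`enrichmentFactor` (default 10) on the pooled targets of the planted
differential miRNAs, so the hypergeometric signal of a planted term is
known to be present and its recovery rate can be measured.

What the generator does *not* emulate: probe cross-hybridization,
plate/port effects, amplification-efficiency differences, correlated
miRNA families, and realistic target-map topology (real maps are highly
non-uniform). Passing recovery tests therefore demonstrates that the
pipeline's inference machinery is correct and calibrated under its own
assumptions — not that those assumptions hold for any particular real
array.

# Reference mode

`runReferenceMode()` starts from the packaged table of the 18 published
differential miRNAs (16 up, fold changes ~17.9 to ~601.9; 2 down, ~0.036
and ~0.072) and runs only the annotation-dependent stages. The published
p-values cannot be reproduced — the raw CT data were never deposited —
so the printed fold changes and direction counts are the reproducible
surface, and the fixture is transcribed to all printed decimal places.

# Numerical and testing choices

Determinism: every stochastic entry point takes a seed and restores the
caller's RNG state; result tables are written with fixed 15-significant-
digit decimal formatting so equal inputs give byte-identical files. The
run manifest records an MD5 hash over the configuration plus the content
hashes of its input files, so the hash changes iff a threshold, a seed
or the data change.

Test problem sizes were chosen to keep the full suite under a minute
while leaving comfortable statistical margins: hyperparameter recovery
uses 20000 features (observed error ~3%, asserted <10%), null
calibration 5000 features against the 99% binomial interval at
alpha = 0.05 plus a Kolmogorov-Smirnov uniformity check, the exhaustive
Fisher oracle covers every 2x2 table with N <= 60 at 1e-10, generator
variance calibration uses 20 seeds of 5000 features (>= 95% must pass KS
at alpha = 0.01), and planted-enrichment recovery 100 seeds at the full
365-assay design (>= 95% must rank the planted term first).

# Known limitations

* The empirical FDR 1 - Nk/T is reported faithfully but is a blunt
  instrument: it is one number per run and says nothing about which
  terms are reliable. The BH q-values emitted alongside are the better
  tool when faithfulness to the original procedure is not required.
* Edge weights operationalize "counted by their differential expression
  values" as |log2 FC|; the original description gives no formula, so
  this is an interpretation (configurable at the data-frame level).
* The miRNA-level test says nothing about target-gene expression;
  enrichment treats all predicted targets of a differential miRNA as
  "differential genes", inheriting every weakness of target prediction.
* Between-group variance heterogeneity is not modeled (the RVM pools
  across groups), and paired designs are out of scope.
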