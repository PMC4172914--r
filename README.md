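# mirArrayDE

Differential expression, gene-set over-representation, and regulatory
network analysis for miRNA profiling on TaqMan-style low-density qPCR
arrays — built for the hardest common case: a few hundred assays, a
handful of endogenous small-RNA controls, and **three biological
replicates per group**.

The package targets researchers analyzing developmental or comparative
miRNA panels (the motivating design is newborn vs adult rat cochlear
sensory epithelium on a 365-assay rodent panel, normalized to the snRNAs
U44 and U48) who need the full path from raw CT values to ranked hub
miRNAs, with every stage testable against planted ground truth.

## What it computes

**Normalization and quantification.** Per sample,
ΔCT = CT − mean(control CTs); per feature,
ΔΔCT = mean ΔCT(comparison) − mean ΔCT(reference) and fold change
2^−ΔΔCT. One PCR cycle is one log2 unit; lower CT is higher expression.

**Random variance model (RVM) t-test.** At n = 3 per group an ordinary
t-test has m = 4 df. The RVM (Wright & Simon 2003) treats per-feature
variances as exchangeable inverse-gamma draws, 1/σ² ~ Gamma(a, b), under
which s²·a·b ~ F(m, 2a) marginally; (a, b) are fitted by maximum
likelihood across all features, the pooled variance is shrunk,

    s̃² = (m s² + 2/b) / (m + 2a),    t = Δmean / sqrt(s̃² (1/n₁ + 1/n₂)),

and t is referred to m + 2a degrees of freedom — the prior buys 2a extra
df. BH q-values follow; selection applies p and fold-change thresholds
and classifies direction (up iff FC > 1).

**Over-representation.** Differential-miRNA target genes are tested
against GO/pathway sets (GMT) with the one-sided Fisher exact test and
the Pearson χ² test (no continuity correction), the enrichment ratio
**Re = (nf/n)/(Nf/N)**, and the run-level empirical
**FDR = 1 − Nk/T**, where Nk counts terms whose Fisher p is strictly
below their χ² p among T tested terms. GO defaults: p < 0.001,
FDR < 0.05.

**Networks.** Bipartite miRNA–gene (edge iff target; weight |log2 FC|)
and miRNA–GO (edge iff a shared gene; weight = shared genes × |log2 FC|)
graphs, with degree-based hub ranking — the key miRNAs and genes are the
highest-degree nodes. Exports: edge-list TSV, node table, GraphML.

**Synthetic ground truth.** A generator emulating the panel design (365
assays + U44/U48, 3 + 3 samples, 16 planted up-regulated features at
17–602 fold, 2 down at 1/28–1/14, inverse-gamma variances) and an
annotation generator with planted enriched terms, so recovery and
calibration are measurable.

## Worked example

```r
library(mirArrayDE)

sim <- simulateCtPanel(panelConfig(seed = 1))
sim$panel
#> CtPanel: 365 assays, 2 controls, 6 samples
#>   groups: adult (n=3), newborn (n=3)
#>   controls: U44, U48

dct <- deltaCt(sim$panel)                      # control-normalized
fc  <- foldChanges(dct, "newborn", "adult")    # 2^-ddCT, adult/newborn
tt  <- rvmTest(dct, reference = "newborn", comparison = "adult")
res <- merge(fc, tt, by = "mirna_id")
res$q_value <- bhAdjust(res$p_value)
de  <- selectDifferential(res)                 # p < 0.05, |FC| >= 2
head(de[, c("mirna_id", "fold_change", "direction", "t", "df",
            "p_value", "q_value")], 5)
#>            mirna_id fold_change direction      t    df   p_value   q_value
#> 289 rno-miR-sim-289       870.1        up 13.075 7.354 2.343e-06 0.0002851
#> 93  rno-miR-sim-093       237.0        up 16.497 7.354 4.459e-07 0.0001628
#> 112 rno-miR-sim-112       201.7        up 14.023 7.354 1.425e-06 0.0002600
#> 227 rno-miR-sim-227       176.9        up  8.571 7.354 4.390e-05 0.0020300
#> 309 rno-miR-sim-309       164.7        up  8.391 7.354 5.064e-05 0.0020536
```

The fitted prior here is a ≈ 1.68, b ≈ 1.23: each feature's test gains
2a ≈ 3.4 effective degrees of freedom (df 7.35 instead of 4). All 18
planted features are recovered at the top of the ranking; at p < 0.05
over 365 features a handful of null features also pass, which is what
the q-value column is for. `runPipeline()` wraps these stages (plus
enrichment and networks) around a YAML config with a reproducibility
manifest, and `simulateStudy()` writes a complete ready-to-run input
set. `runReferenceMode()` analyzes the packaged published 18-miRNA
fold-change table (16 up, max 601.87; 2 down, min 0.0359) when only the
printed results, not raw CTs, are available. A thin command-line wrapper
lives at `inst/scripts/mir_pipeline.R`.

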