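---
title: "Classifying the fate of past-cue expression plasticity during adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the fate of past-cue expression plasticity during adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastiscan)
```

## The question and the design

Coastal populations of *Silene uniflora* are plastic to salinity, a cue of
their ancestral habitat. Derived populations on zinc-contaminated mine
waste face a chemically different stressor. `plastiscan` implements a
contrast-based framework for asking whether the ancestral *past-cue*
(salt) plasticity was lost, re-used, or hard-wired during adaptation to
the *new* cue (zinc).

The design it analyzes is two experiments over the same four populations
(two independent coast/mine pairs, W and E): a salt experiment (control
vs 0.1 M NaCl) and a zinc experiment (control vs zinc), each with three
individuals per population per treatment pooled into one RNA-seq sample —
24 samples per experiment. Three families of per-gene direction calls are
derived:

* `P(pop, cue)`: treatment vs control within each population
  (individual-paired), for the salt cue in the salt experiment and the
  zinc cue in the zinc experiment;
* `D(pair, treatment)`: mine vs coast within each pair, in control, salt
  and zinc treatments;
* `X(pop)`: control vs control between the two experiments, per
  population.

All calls are ternary (`up` / `down` / `ns`) at a BH-adjusted level
`alpha` (default 0.05, the boundary counting as significant). `X` defines
the *comparable universe*: genes with no significant control difference
between experiments. Classification rules (shared-direction coastal salt
plasticity, its relation to coastal and mine zinc plasticity and to the
constitutive mine-vs-coast divergence) then assign each gene to
preadaptive plasticity, cue transfer, genetic adoption, genetic
assimilation, or a residual class. The four named categories are mutually
exclusive by construction; the classifier asserts this on every run and
aborts rather than picking silently if the invariant were ever violated.

## The differential-expression engine

The engine is deliberately compact. Counts are normalized by
median-of-ratios size factors (reference genes are those with no zero
count; a pseudo-count fallback is available via `pseudo_reference`).
Per-gene NB dispersions (`Var = mu + alpha * mu^2`) are estimated by
method of moments on normalized counts pooled within design cells,
shrunk toward a least-squares `a0 + a1/mu` trend with weight
`df / (df + prior)` (prior 4 by default, chosen for three-replicate
designs). A contrast fits the two cell means, floors them at 0.5
normalized counts so fold changes stay finite, and tests
`log2fc / se` with the standard error from the NB variance function.

Two numerical choices matter in small designs:

* **Reference distribution.** Because the dispersion entering the
  standard error is estimated, the Wald statistic is referred to a t
  distribution with moderated degrees of freedom — the
  dispersion-estimation residual df plus the shrinkage prior df — rather
  than a normal. On a 20,000-gene null simulation (3 vs 3, dispersion
  0.05) the normal reference inflates the far tail about two-fold
  (P(p ≤ 0.005) ≈ 0.011), enough to push empirical FDR above 1.5× the
  nominal level; the moderated t restores uniformity (KS distance ≈ 0.02)
  at the cost of mild conservatism. A known scalar dispersion uses the
  normal reference.
* **Pairing.** The paired plasticity model is implemented as
  within-individual mean-centering before the contrast. In a balanced
  design this leaves the cell means — and therefore the fold change and
  its model-based standard error — unchanged; it matters only when
  per-individual baselines shift and residual-based diagnostics are used.
  The flag `paired = FALSE` disables it.

BH adjustment is computed over exactly the tested gene set of each
contrast, so the comparable-universe filter is applied *before* the P and
D contrasts are adjusted.

An adapter point exists for external DE engines: any per-contrast table
with `gene_id`, `log2fc`, `padj` can be turned into calls with
`call_genes()` and assembled into a catalog, since every downstream rule
consumes `direction_call` tables only.

## The synthetic study and what it does (not) show

`simulate_experiments()` draws both experiments from one set of per-gene
baselines (log-normal, default meanlog `log(400)`, sdlog 1) with NB noise
(`alpha(mu) = a0 + a1/mu`, default flat 0.05) and per-sample log-normal
depth factors (sdlog 0.2). Planted classes receive effects of magnitude
`effect_log2fc` (default 2) with a random sign per gene, under the sign
constraints that define each class; for cue transfer and genetic adoption
the coastal zinc response is absent or opposite with equal probability,
mirroring the observation that reversed ancestral new-cue plasticity is
common. Default class proportions keep 88% of genes null and spread the
remainder over the six effect classes, including lineage-specific
responses that must *not* be called (they are never shared across a
pair). Three individuals per population per treatment reproduce the
24-pool design; the NB dispersion is the between-individual biological
variance, and no separate individual random effect is planted.

Because cross-experiment control means are equal by construction (a
constitutive mine shift applies to both experiments alike), the
comparable-universe filter removes essentially only false positives in
simulation. Real data can violate this — batch effects between
experiments performed years apart are exactly what the `X` filter is for
— so passing synthetic tests demonstrates the machinery's correctness,
not robustness to cross-experiment confounding. Likewise the generator
does not emulate gene-gene correlation, outlier samples, or
mean-dispersion relationships fitted from real tissue; dispersion
defaults are stated, not estimated from the deposited reads.

Recovery is scored on the analyzed universe: planted genes removed by the
count filter are reported as `n_filtered`, not counted against recall,
matching the convention that all category percentages refer to the
comparable gene set.

## Resampling statistics

* **Overlap randomization.** The observed statistic is the
  direction-matched shared-gene count between two call sets; the null
  redistributes one set's up/down labels uniformly over the universe
  without replacement, with the add-one p-value
  `(1 + #{perm ≥ obs}) / (n_perm + 1)`. The implementation is checked
  against an exhaustive enumeration oracle on small universes.
* **Chance proportions.** The chance rate for a category rule is
  estimated by permuting every contrast's calls independently across
  genes, preserving margins while breaking dependence. The one-sample
  chi-square (`prop.test`) then compares the observed category count in
  its denominator set against that rate; a zero permutation estimate is
  floored at the add-one bound `1 / (n_perm × n_genes + 1)`.
* **P~ST~–F~ST~.** For constitutive divergence the trait is
  `log2(normalized control count + 0.5)`; for plastic divergence it is
  the per-individual log2 zinc/control ratio (`log_ratio = FALSE` gives
  the raw ratio). `PST = (c/h² σ²_B) / (c/h² σ²_B + 2 σ²_W)` with
  `c/h² = 1` by default — the conservative convention when heritability
  is unknown — and the exceedance criterion compares the point estimate
  to the empirical `1 − alpha` F~ST~ quantile (a stricter CI-based mode
  would compare the bootstrap lower bound). Percentile bootstrap CIs
  resample within populations.

## Decisions on under-specified points

* The count floor ("remove sample counts of < 10") is read as removing a
  gene whose *any* sample count is below the floor within an experiment —
  the stricter, rectangular interpretation; `mode = "total"` implements
  the row-sum alternative.
* The comparability filter demands `ns` in *all four* populations'
  `X` contrasts (strictest reading); `comparability = "pooled"` tests
  pooled controls instead.
* Constitutive divergence `D(pair, control)` uses the zinc experiment's
  control samples, matching the experiment in which constitutive change
  was originally defined; `control_divergence_from = "salt_expt"`
  switches.
* The cue-transfer denominator is the subset of evolved-zinc-plasticity
  genes whose shared coastal zinc call differs (in significance or
  direction) from the shared mine zinc call — only such genes have
  *changed* plasticity.
* "Not the same response" is evaluated on shared coastal calls: coasts
  disagreeing about the zinc direction counts as "not the same".
* Preadaptive plasticity uses the strict all-four-populations rule.
* Integer percentages round half away from zero; two-decimal percentages
  use standard two-decimal rounding. These conventions reproduce the
  published 31/24/85 and 86.21/4.14/0.67/47.34 values from their printed
  numerators and denominators.
* Ratios with empty denominators (empty gene sets) yield `NA` flagged by
  a `defined` column, never errors.

## Reproducibility and problem sizes

A single integer seed drives everything; stage-level child seeds are
fanned out deterministically so stages can be rerun in isolation, and two
runs with the same configuration produce byte-identical classification
reports. The shipped validation suite runs the generator at 10,000 genes
with 2% planted per headline class for recovery (precision and recall
≥ 0.85 per class), 2,000-gene null simulations for calibration, 10,000
permutations against the enumeration oracle, and 10,000 loci for
F~ST~-quantile calibration; these sizes give Monte-Carlo error well below
the asserted margins while keeping a full run in the order of a minute.

## Known limitations

The engine omits Cook's-distance outlier handling, independent filtering
and MAP fold-change shrinkage; it is a calibrated reduced workflow, not a
drop-in replacement for a full DE package on messy real data. The
classifier requires exactly two population pairs. P~ST~ inference
inherits the usual caveat that `c/h²` is unknown for expression traits;
conclusions should be checked across a range of that scalar. Chance
proportions are permutation-based estimates, so reported chi-square
statistics depend on the permutation budget when the true chance rate is
effectively zero.
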