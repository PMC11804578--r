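# plastiscan

Past-cue expression plasticity and its fate during adaptation.

## The problem

Populations that colonize a novel environment carry with them plastic
responses evolved under *past* environmental cues. In the coastal plant
*Silene uniflora*, coastal populations are plastic to salinity; mine-waste
populations derived from them have adapted to zinc-contaminated soil they
never co-experienced with salt. `plastiscan` asks what happens to that
ancestral past-cue plasticity during adaptation to the new cue, using paired
RNA-seq experiments (control vs salt in one experiment, control vs zinc in
the other) across two independent coast/mine population pairs.

Each gene in the cross-experiment comparable set is classified from a
catalog of direction calls — within-population plasticity `P(pop, cue)`,
mine-vs-coast divergence `D(pair, treatment)` and cross-experiment control
comparability `X(pop)` — into:

- **preadaptive plasticity** — significant same-direction responses to both
  cues in all four populations (ancestral plasticity already suits the new
  cue);
- **cue transfer** — shared coastal salt response of direction *d*, coastal
  zinc response ≠ *d*, and evolved mine zinc plasticity of direction *d*
  (the old salt response is now triggered by zinc);
- **genetic adoption** — shared coastal salt response *d*, constitutive
  mine-vs-coast change of direction *d*, no mine zinc plasticity, coastal
  zinc response ≠ *d* (the old plastic value became constitutive);
- **genetic assimilation** — constitutive change matching the shared coastal
  zinc response with mine zinc plasticity lost (ancestral new-cue plasticity
  canalized).

Significance against chance uses a direction-matched overlap randomization
test, a one-proportion chi-square against a permutation-estimated chance
rate, and a P<sub>ST</sub>–F<sub>ST</sub> screen

P<sub>ST</sub> = (c/h² · σ²<sub>B</sub>) / (c/h² · σ²<sub>B</sub> + 2σ²<sub>W</sub>)

compared with the upper tail of a genome-wide neutral F<sub>ST</sub>
distribution.

Differential expression runs on a compact negative-binomial engine
(median-of-ratios normalization, method-of-moments dispersions shrunk to an
`a0 + a1/μ` trend, moderated-t Wald contrasts, Benjamini–Hochberg FDR), and
every stage is exercised by a synthetic generator that plants the gene
classes above with known directions — so the whole pipeline is testable
without sequencing data.

## Worked example

```r
library(plastiscan)
run <- run_full(list(analysis = list(seed = 1, n_permutations = 1000),
                     simulation = list(n_genes = 4000)))
print(run)
```

```
plastiscan run: 3959 comparable genes
  coast_salt_plastic         301
  mine_salt_plastic          149
  evolved_zinc_plasticity    112
  constitutive_ec            146
  preadaptive                75
  cue_transfer               70
  genetic_adoption           72
  genetic_assimilation       74
```

3,959 of 4,000 simulated genes survive the count and cross-experiment
filters. 301 genes are salt-plastic in both coasts, of which only 149
remain salt-plastic in both mines (loss of past-cue plasticity). 70 of the
112 genes with evolved zinc plasticity show cue transfer, and 72 of the 146
constitutively diverged genes show genetic adoption — close to the planted
2% of 4,000 per class (the remainder were filtered or missed one contrast).

```r
r <- run$randomization$coast_salt
sprintf("coast salt overlap: observed %d, expected %.1f, p = %.2g",
        r$observed_overlap, r$expected_overlap, r$p_value)
#> "coast salt overlap: observed 301, expected 13.8, p = 0.001"

print(run$recovery[, c("class", "precision", "recall", "f1")])
#>                 class precision recall    f1
#>           preadaptive         1  1.000 1.000
#>          cue_transfer         1  0.921 0.959
#>      genetic_adoption         1  0.973 0.986
#>  genetic_assimilation         1  0.987 0.993
```

The shared coastal salt-plastic set is ~22× the chance expectation
(randomization p at its permutation floor), and every planted category is
recovered with precision 1 and recall ≥ 0.92.

A shell wrapper with `simulate`, `classify` and `run-all` subcommands is
installed as `exec/plastiscan`.

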