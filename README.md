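# lateralize

Hemispheric specialization for the direction of visual motion, measured
from event-related potentials (ERPs) and related to molecular covariates.

## The problem

A grating in central vision that appears to scroll left or right evokes a
motion-sensitive N2 component (~190 ms, negative-going) that is larger
over the hemisphere *contralateral* to the motion direction. In typical
adults this direction sensitivity is strongly right-lateralized; in
Williams syndrome (WS) it reverses toward the left hemisphere, and the
residual expression and promoter methylation of single deleted genes
(notably *BUD23*) track that reversal subject by subject. This package is
for researchers who need that analysis chain as tested, reusable code:
EEG preprocessing, ERP component measurement, laterality metrics,
batch-aware molecular correlation, and the classical inference around
them — plus a synthetic cohort generator so every stage can be validated
end to end with known ground truth and no data download.

## The model

For each subject, the N2 mean amplitude `A_h(d)` is measured 155–195 ms
over left (`P5, PO3, PO7`) and right (`P4, PO4, PO8`) parieto-occipital
sets for scroll-left (SL) and scroll-right (SR) motion. Each hemisphere's
sensitivity is its contralateral-minus-ipsilateral difference, and the
Laterality Index is their difference:

    S_R = A_RH(SL) − A_RH(SR)
    S_L = A_LH(SR) − A_LH(SL)
    LI  = S_R − S_L

Negative values (the N2 being negative-going) mean greater sensitivity;
negative LI means right-hemisphere dominance, positive left, zero equal
sensitivity without specialization. Expression features are standardized
within acquisition batch (z-scores) before pooling; correlations with
laterality phenotypes use directional Pearson tests
(`t = r·sqrt(n−2)/sqrt(1−r²)`) with Bonferroni/Holm adjustment per
declared family. Group inference uses pooled-variance t tests,
uncorrected 2×2 chi-square, and a split-plot mixed ANOVA (one between
factor, up to two 2-level within factors) implemented from first
principles and anchored to the `F = t²` identities.

## Worked example

Simulate a demonstration-scale cohort (10 + 10 subjects, 40 trials per
condition), run the full pipeline, and inspect the laterality summary:

```r
library(lateralize)
cfg <- defaultPipelineConfig(seed = 42L)
bundle <- runPipeline(cfg)
bundle$summary
#> Laterality cohort summary
#>   specialization (% within group):
#>   group          class     n   pct
#>      TC RH_specialized     7    70
#>      TC LH_specialized     3    30
#>      WS LH_specialized     6    60
#>      WS RH_specialized     4    40
#>   S_R vs S_L correlation per group:
#>   group          r     n         t          p
#>      TC -0.6567366    10 -2.463178 0.03912441
#>      WS -0.6382427    10 -2.344947 0.04705093
#>   between-group LI t(18) = -2.169, p = 0.0437
```

Even at this small scale the simulated cohort shows the structure the
method is designed to detect: most controls are right-hemisphere
specialized and most WS subjects left, the two hemispheric sensitivities
are inversely related within each group (r ≈ −0.65), and the groups
differ in LI (t(18) = −2.17). The N2 ANOVA from the same run shows the
direction-by-hemisphere interaction that defines contralateral
sensitivity (F(1,18) = 180.8, p = 7.9e-11):

```r
bundle$anovas[analysis == "N2 amplitude 2x2x2"]
```

Stage functions are exported individually (`simulateCohort()`,
`preprocessEpochs()`, `measureN2()`, `hemisphereSensitivity()`,
`lateralityIndex()`, `zscoreWithinBatch()`, `correlateGrid()`,
`mixedAnova()`, ...), and a command-line wrapper lives at
`inst/scripts/run_pipeline.R` (`--config`, `--seed`, `--out-dir`,
`--stage`, `--print-config`). See the vignette
(`vignettes/motion-laterality.Rmd`) for the models, defaults and design
decisions.

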