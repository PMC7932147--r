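# posthypoxia

Statistical pipeline for the first 24 hours after severe systemic
hypoxia in the mouse: multiplex (Luminex xMAP) immune profiling of
plasma and retina with an exact small-sample permutation screen, and the
companion OCT retinal-layer and histology group statistics. A seeded
synthetic-data generator with known ground truth makes every stage
testable without external data.

Intended for biostatisticians and vision/neuro-inflammation researchers
analyzing small-n multiplex cytokine panels (n ≈ 4–5 per group), where
asymptotic tests are unreliable and exact inference is the natural tool.

## The method

For each of the 39 analytes, well-level mean fluorescence intensities
(MFI) are duplicate-averaged and normalized against the Chex #4
internal-control bead relative to the plate median (well-level
multiplicative drift scales analyte and control beads identically, so
this removes it exactly). The treated group (1 h posthypoxia) is then
compared with controls by a fully enumerated permutation test: over all
`N = choose(n1+n2, n1)` label assignments, the exact p-value is `k/N`
with the observed assignment always counted. A **primary hit** attains
the smallest possible p-value, which for no-ties data is exactly
*complete separation* — no overlap between the groups' values. At the
5-vs-5 design,

    p_min = 2 / C(10,5) = 2/252 ≈ 0.0079  →  printed 0.008,

which is why every primary hit carries the same p-value. A **secondary
screen** applies the exact Mann-Whitney U test with Benjamini-Hochberg
FDR control at q = 0.1 across the panel (within tissue); secondary hits
are BH-significant analytes not already primary. Hit sets from plasma
and retina are partitioned Venn-style, and sample dendrograms
(log, z-score, Euclidean, average linkage) are scored for segregation of
the 1 h group by a two-cluster cut.

The structural arm derives retinal layers (INL-to-RPE = TRT − GCC, μm),
reports mean ± SEM, and runs the classical tests: paired t on the same
eyes, one-way ANOVA + Tukey HSD (including a summary-statistics
reconstruction from printed mean/SEM/n triples), two-way type-II ANOVA
for layer × group counts, and Pearson correlation.

## Worked example

```r
library(posthypoxia)

min_attainable_p(5, 5, "two")$rendered
#> "0.008"

b <- run_pipeline(run_config(seed = 1))
subset(b$screens$plasma, primary_hit, select = c(analyte, ratio, perm_p))
#>  analyte ratio  perm_p
#>      IL6  2.09 0.00794
#>      IL9  1.31 0.00794
#>     IL13  1.82 0.00794
#>    MIP1A  1.48 0.00794
#>      IL4  1.57 0.00794
#>     VEGF  1.90 0.00794
b$venn$shared
#> [1] "VEGF"
round(b$segregation, 3)
#> plasma retina
#>  0.800  0.667
```

The simulated cohort carries the published 1 h fold effects as ground
truth (ten plasma analytes, folds 1.26–2.19; four retinal, 1.24–2.11).
At the default biological noise (CV 0.1) the large-fold analytes
separate completely — each at the exact floor 2/252 — while folds below
about 1.4 separate only intermittently, so a single simulated plate
typically recovers part of the configured plasma list; the retina list
(larger folds) is recovered in full. The segregation scores are the
two-cluster classification accuracies for the 1 h group.

The numbered drivers under `analysis/` run the same workflow as a
narrative — `01_simulate_cohort.R` (plates, OCT, histology),
`02_immune_screen.R` (normalization, exact screen, Venn),
`03_clustering.R` (dendrograms, segregation), `04_oct_histology.R`
(paired tests, deltas, ANOVA/Tukey, TUNEL two-way ANOVA) — and write
their tables under `results/`.

## Layout

```
R/                  package code (generator, IO, normalization, exact
                    tests, screen, clustering, structural statistics,
                    pipeline)
analysis/           numbered narrative drivers over the package
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/          methods vignette (model, assumptions, design choices)
```
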