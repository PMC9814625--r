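# contextflux

Transcriptome-contextualized metabolic modeling and discriminative
reaction discovery in R.

## What problem this solves

Bulk transcriptomes of two patient groups (e.g. a disease cohort vs.
controls) are noisy and heterogeneous at the single-gene level, yet the
groups may differ systematically in *which metabolic reactions they
actually use*. `contextflux` turns per-sample gene abundances plus a
genome-scale metabolic network reconstruction (stoichiometry **S**, flux
bounds, gene–protein–reaction rules, a biomass objective) into a ranked
list of reactions whose flux separates the groups — the kind of output a
systems-biology group would mine for candidate biomarkers or drug targets.

The pipeline, per patient and then across the cohort:

1. **Gene overlay.** Keep genes present in both model and data; remove
   every reaction whose GPR rule cannot be satisfied (`and` = complex,
   `or` = isozymes; reactions without genes are always kept).
2. **Transcript-weighted parsimonious FBA.** With FBA optimum
   *Z* = max *v*<sub>bio</sub> s.t. **S** *v* = 0, *lb* ≤ *v* ≤ *ub*,
   minimize Σ<sub>r</sub> *w*<sub>r</sub>|*v*<sub>r</sub>| subject to
   *v*<sub>bio</sub> ≥ *f*·*Z*, where *w*<sub>r</sub> = 1 −
   *a*<sub>r</sub>/max(*a*) penalizes reactions with weak transcript
   support and *f* = 1.0 by default.
3. **FVA pruning.** Reactions whose entire flux range under the objective
   floor and the parsimony cap lies within ±1e-6 of zero are pruned; the
   rest form the patient's contextualized model.
4. **Flux sampling.** 50–500 feasible flux vectors per patient by seeded
   artificial-centering hit-and-run over the constrained polytope.
5. **Repeated random-forest validation.** 100 splits; in each, classes are
   balanced by under-sampling patients, patients (not rows) are split
   80/20 stratified by group, a 100-tree forest is trained on the training
   patients' flux points and scored on the test patients' points.
6. **Aggregation, testing, grouping.** Splits with F1 > 0.70 contribute
   their top-20 reactions by impurity importance; the consensus ranking is
   compared between groups with the two-sided Mann–Whitney U test
   (significant at raw p < 0.05, BH-adjusted p reported alongside) and
   grouped into subsystem families.

A synthetic-data module generates toy networks with redundant pathways to
biomass and two-group cohorts with planted differential pathway usage, so
the whole pipeline is testable against ground truth with no downloads.

## Worked example

```r
library(contextflux)

paths <- write_fixture_bundle(tempfile(), synthetic_spec(seed = 11))
cfg <- run_config(model = paths[["model"]], abundance = paths[["abundance"]],
                  labels = paths[["labels"]], master_seed = 11)
report <- run_pipeline(cfg)
```

The run logs each stage and prints:

```
loaded 18 reactions, 40 profiles
overlay: 16/16 genes shared; 0 reactions removed
contextualized 40 patients; mean reactions pruned 13.0
repeated validation: mean accuracy 1.000 over 100 splits
Discriminative reaction report
  mean accuracy 1.000 over 100 splits (100 qualifying)
  mean reactions pruned per patient: 13.0
  top reactions:
  reaction frequency mean_importance rank
1     P1_2       100       0.1720962    1
2     P2_2       100       0.1694376    2
3     P2_1       100       0.1666392    3
4     P1_3       100       0.1647380    4
5     P1_1       100       0.1646468    5
```

Reading this: each patient's contextualization pruned 13 of 18 reactions —
the ten flux-incapable background reactions plus the three reactions of
whichever planted pathway that patient's transcripts disfavor. The forest
separates cases from controls perfectly in all 100 splits, and the
consensus ranking is headed by the six planted pathway reactions
(`P1_*` case-favored, `P2_*` control-favored). `report$comparisons` then
shows, e.g. for `P1_2`, median flux 10 in cases vs 0 in controls with
Mann–Whitney p < 0.05, while the shared uptake and biomass reactions
(identical flux in both groups) are correctly non-significant. With
`outdir` set, `ranking.tsv`, `comparisons.tsv`, `families.tsv`,
`metadata.json` and one flux-distribution plot per subsystem family are
written to disk, byte-identical across re-runs with the same master seed.

A command-line wrapper with `simulate` and `run` subcommands lives at
`inst/scripts/contextflux.R`.

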