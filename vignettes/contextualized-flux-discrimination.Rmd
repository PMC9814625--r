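---
title: "Transcriptome-contextualized flux modeling and discriminative reaction discovery"
author: "contextflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-contextualized flux modeling and discriminative reaction discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two patient groups — say, a disease cohort and controls — may run their
metabolism differently even when a gene-by-gene comparison of their
transcriptomes is inconclusive. Constraint-based metabolic modeling offers a
way to translate transcript abundances into statements about *reaction use*:
a genome-scale metabolic network reconstruction (GENRE) fixes the
stoichiometry S, flux bounds, and gene–protein–reaction (GPR) rules; flux
balance analysis (FBA) then finds flux states `v` satisfying the
steady-state assumption `S v = 0` within bounds while maximizing a biomass
objective. `contextflux` implements a full pipeline on top of this idea:

1. **Overlay** — genes measured in the data and present in the model define
   a presence set; reactions whose GPR rule cannot be satisfied by that set
   are removed.
2. **Contextualization** — per patient, transcript abundances become
   parsimony weights, a transcript-weighted parsimonious FBA (pFBA) finds
   the cheapest flux state that still attains the objective, and flux
   variability analysis (FVA) under the resulting constraints prunes every
   reaction that cannot carry flux in that state.
3. **Sampling** — feasible flux vectors are drawn from each patient's
   constrained solution polytope by hit-and-run sampling.
4. **Discrimination** — repeated random-forest classification of the
   sampled flux points, with patient-level train/test splits and
   class-balancing under-sampling, ranks reactions by how consistently they
   separate the groups.
5. **Reporting** — top reactions are compared between groups with the
   two-sided Mann–Whitney U test and grouped into subsystem families.

## The model, step by step

### Transcripts to weights

A reaction's transcript support is computed from its GPR rule with the
standard semantics: `and` nodes (enzyme complexes) take the **minimum** of
their children — a complex is limited by its scarcest subunit — and `or`
nodes (isozymes) take the **maximum**. A gene missing from the data counts
as zero. Reactions without any gene association (transport, exchange, the
biomass pseudo-reaction) receive the **median** of the gene-backed reaction
abundances of that sample, a deliberately neutral value: they should
neither attract nor repel flux on transcriptomic grounds.

Abundances `a_r` map onto weights by `w_r = 1 − a_r / max(a)`, the simplest
antitone map onto [0, 1]: the best-supported reaction is free to use, an
unsupported one costs one unit of penalty per unit of flux.

### Weighted parsimonious FBA

With the FBA optimum `Z` in hand, the parsimony stage minimizes
`Σ_r w_r |v_r|` subject to `S v = 0`, the bounds, and
`v_objective ≥ fraction · Z`. Each reversible reaction is split into
non-negative forward and backward parts, which linearizes the weighted-L1
objective exactly. `fraction` defaults to **1.0** — full objective
attainment, the appropriate choice for a hypermetabolic disease state — with
0.8 available as the conventional alternative.

### Pruning by FVA under a parsimony cap

A single pFBA solution is a fragile basis for pruning: LP solvers return an
arbitrary vertex of the optimal face, so which of two equally cheap routes
carries the flux is solver luck. The pruning decision therefore uses FVA
under two carried-forward constraints — the objective floor and the
parsimony cap `Σ w |v| ≤ (1 + slack) · p*` — and prunes exactly the
reactions whose whole attainable range lies within ±1e-6 (the pruning
tolerance) of zero. Any reaction with *some* near-optimal state that uses
it survives.

The cap slack deserves a word, because the two tolerances interact. A
relative slack `s` lets a reaction with weight `w` carry up to `s·p*/w`
flux while staying under the cap. If that exceeds the pruning tolerance,
nothing is ever pruned: every transcriptionally disfavored route is
retained with a vanishing but nonzero range. The slack therefore defaults
to **1e-9** — enough to keep the optimal face strictly feasible under
round-off (the parsimony optimum is computed to ~1e-12 relative accuracy),
and orders of magnitude below the level at which it would leak flux past
the pruning tolerance.

### Flux sampling

Each patient's constrained polytope — mass balance on the retained
reactions, bounds, objective floor, parsimony cap — is explored with an
artificial-centering hit-and-run walk: 100 burn-in steps, thinning 10,
directions drawn from the null space of S (after burn-in, through randomly
chosen earlier points re-centered on the running mean). Two implementation
details matter:

* The walk is parameterized in null-space coordinates (`v = v0 + N z`), so
  mass balance holds exactly at every step rather than drifting over
  thousands of floating-point additions.
* Coordinates whose FVA width is below the pruning tolerance are treated as
  equality-pinned when building the direction basis. Without this, in a
  polytope whose affine hull is lower-dimensional than the null space of S,
  every random chord immediately hits a wall and the walk stalls.

The weighted-L1 cap is convex, so its feasible stretch along any chord is
an interval; it is located exactly from the piecewise-linear breakpoints.
A zero-volume polytope (a fully pinned model — common at `fraction = 1`
with informative transcripts) yields n copies of the parsimonious vertex
with a warning.

The number of samples per patient follows the mean FVA-range width, rounded
and clamped into [50, 500]: wide permissible ranges earn more samples.

### Repeated random-forest validation

Flux points from all patients form one feature table (features = union of
retained reactions; a reaction pruned for a patient contributes exact zeros
to that patient's rows). Each of the (default 100) splits: balance the
groups by randomly under-sampling the majority's patients; split *patients*
80/20 stratified by group; train a 100-tree random forest (Gini impurity,
√p features per node) on all training-patient rows; evaluate row-level
accuracy and F1 (positive class = case) on all test-patient rows. Keeping
every row of a patient on one side of the split prevents the leakage that
row-level splitting would invite, since rows of one patient are highly
correlated.

Splits with F1 strictly above 0.70 qualify; each contributes its top-20
reactions by normalized impurity importance. The final ranking orders
reactions by qualification frequency, then mean importance, then reaction
id — a deterministic total order. F1 (not accuracy) is the qualification
metric; accuracy is reported alongside.

### Group comparison and families

For each top reaction the case rows are compared against the control rows
with the two-sided Mann–Whitney U test: exact permutation distribution for
combined sample sizes ≤ 16 without ties, tie-corrected normal approximation
with continuity correction otherwise. Significance is called on the raw
p-value at α = 0.05 (the workflow's decision rule); Benjamini–Hochberg adjusted
p-values are reported as a supplementary column. By default the test pools
all flux points of a group, matching how the flux distributions are
plotted; a per-patient-mean mode is available (`pooling = "patient_mean"`)
because pooling inflates n — with tens of thousands of pooled points,
minuscule shifts reach significance, which is worth remembering when
reading the p-values. Reactions are finally grouped into families by their
subsystem annotation, with an explicit override map taking precedence and
`"Unassigned"` as the fallback.

## The synthetic benchmark

`make_toy_network()` + `simulate_cohort()` generate the ground-truthed
inputs used throughout the tests: a bounded uptake (0–10 flux units)
feeding two stoichiometrically redundant three-reaction pathways to
biomass, ten background reactions arranged as internal two-step loops that
can never carry net steady-state flux toward biomass, and one unique gene
per reaction. Cases carry a 4-fold transcript increase on pathway 1 genes
and a 4-fold decrease on pathway 2 (controls mirrored), under log-normal
noise (σ = 0.5) on a baseline of 10 RPKM-like units, 20 patients per
group. Because the two routes are metabolically equivalent, which one is
used is decided *purely* by transcript-guided parsimony — precisely the
situation in which reactions become discriminative between groups. With
`effect_fold = 1` the groups are exchangeable, giving a null cohort.

What the generator deliberately does **not** emulate: genome-scale network
size, many-to-many GPR rules in the cohort (complex rules are exercised in
unit tests), library-size or batch effects, and count noise. Passing the
end-to-end tests therefore shows the machinery is sound — pruning follows
the planted transcripts, the classifier recovers the planted reactions,
null cohorts yield chance accuracy — not that effect sizes on real tissue
data will be as clean.

One property of the null benchmark is worth stating plainly: with 20+20
patients, an 80/20 split leaves 8 test patients, and under the null each
patient's flux signature is essentially a fair coin. Single-split F1 then
exceeds 0.70 by chance in a nontrivial fraction of splits, so across 100
splits a handful of spurious "qualifying" splits is the expected outcome,
not a defect; protection against false discoveries comes from the
*aggregation* across splits (a chance-qualifying split contributes noise,
not consensus), and from the group-level Mann–Whitney test downstream.

## Numerical choices

* **LP solver.** All of FBA/FVA/pFBA run on an in-package two-phase dense
  simplex (Dantzig entering rule with index tie-breaks, Bland's-rule
  restart as the anti-cycling safeguard, phase-1 artificials, redundant
  equality rows dropped via QR on the augmented matrix). It is fully
  deterministic: the same model always returns the same vertex. Problems at
  the intended scale (tens of reactions) solve in well under a millisecond.
  Infeasibility and unboundedness raise typed errors.
* **Tolerances.** Feasibility 1e-9 (solver), mass-balance residual 1e-6
  (accepting a flux vector), pruning 1e-6 absolute flux, cap slack 1e-9
  relative (rationale above).
* **Infinite bounds** are capped internally at ±1e6; an optimum pinned at
  the cap is reported as unbounded.
* **Degenerate ties.** Equal weights on parallel routes leave the split of
  flux between them undetermined; pruning handles this correctly (both
  routes retained, since each can carry flux at the optimum) and the
  sampler explores the tie segment.
* **Seeds.** Every stochastic stage (cohort simulation, sampling,
  under-sampling, patient splits, forests) derives its seed
  deterministically from one master seed; two runs with the same inputs and
  master seed produce byte-identical TSV reports.

## Design choices that were genuinely open

* **min/max GPR abundance semantics** and the **linear antitone weight
  map**: the standard community conventions, frozen here as the simplest
  choices faithful to the parsimony principle, and documented.
* **One contextualized model per patient**, not per group: the
  classification stage consumes per-patient flux points, so per-patient
  models are the only coherent reading.
* **Pruning via FVA under the parsimony cap** rather than via the single
  pFBA vertex: robust to alternate optima (see above).
* **Structural gene presence** (a gene is "present" if it has a row in the
  table, even at abundance 0): the overlay removes unmeasured genes, not
  lowly expressed ones; expression levels enter later, through the
  weights. The overlay report records all overlap counts for transparency.
* **Aggregation by frequency-then-mean-importance**: frequency across
  qualifying splits is the most conservative consensus; mean importance
  only breaks ties.
* **No on-disk contextualization cache**: at package scale the LP stage
  costs seconds per cohort, so a hash-keyed cache would add failure modes
  without measurable benefit.
* **Problem sizes in the test suite**: oracle comparisons use networks of
  up to 10 reactions (vertex enumeration stays exhaustive), end-to-end
  checks use the default 20+20 cohort with 100 splits across 10 master
  seeds — large enough to exercise every stage meaningfully, small enough
  to iterate on.

## Limitations

* The LP core is a dense tableau simplex: appropriate for toy-to-moderate
  networks, not for genome-scale reconstructions with thousands of
  reactions, where a sparse revised simplex or interior-point solver (and a
  sparse FVA) would be required.
* Pooled Mann–Whitney p-values scale with the number of sampled flux
  points, not the number of patients; use `pooling = "patient_mean"` for a
  patient-level test.
* The contextualization stage assumes a single declared biomass objective
  and positive attainable growth; models without a positive optimum are
  rejected rather than analyzed.
* SBML support is read-only (Level 3 with the fbc package); COBRA-JSON is
  the canonical, round-trip-safe dialect.

## A minimal run

```{r example}
library(contextflux)

paths <- write_fixture_bundle("bench", synthetic_spec(seed = 11))
cfg <- run_config(
  model = paths[["model"]], abundance = paths[["abundance"]],
  labels = paths[["labels"]], outdir = "bench_out", master_seed = 11
)
report <- run_pipeline(cfg)
report$ranking$ranking   # aggregated discriminative reactions
report$comparisons       # Mann-Whitney group comparison of the top reactions
```
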