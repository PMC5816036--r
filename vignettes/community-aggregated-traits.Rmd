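---
title: "Community-aggregated trait analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-aggregated trait analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(catraits)
```

## The problem

Predictive functional profiling (e.g. PICRUSt on 16S rRNA profiles) turns a
community survey into a sample × KEGG-ortholog (KO) count table: for every
sample, predicted copy counts of thousands of cross-species gene functions.
`catraits` takes such a table for a factorial soil microcosm experiment —
soil compartment (bulk vs rhizosphere) crossed with cadmium dose (0, 20,
100 mg Cd kg⁻¹ soil) — and asks an ecological question of it: do the
functional changes induced by the rhizosphere and by Cd stress follow
Grime's Competitor / Stress-tolerator / Ruderal (CSR) triangle of life
strategies?

The pipeline has four statistical stages, each exposed as ordinary
functions and chained by `run_pipeline()`:

1. **KO-level differential enrichment** between each treatment cell and
   the uncontaminated bulk-soil baseline (negative-binomial Wald test).
2. **Pathway-level enrichment calls** by a subset-resampling (bootstrap
   percentile) null on KO hits, plus an **under-representation screen**.
3. **CSR classification** of called pathways via a frozen trait registry.
4. **CSR net-change scores** per treatment — the coordinates of the
   three-dimensional trait representation.

## Stage 1: KO-level negative-binomial Wald test

Counts for KO *i* in sample *j* are modelled as
NB(μ·s<sub>j</sub>, α) with `Var = μ + αμ²`. Library-size differences are
removed by median-of-ratios size factors (`estimate_size_factors()`): the
per-KO geometric mean over samples forms the reference (KOs with any zero
count are excluded; if none survives, an explicit error points at the
`pseudo_count` fallback), and a sample's factor is the median ratio of its
counts to the reference. All downstream statistics are invariant to a
common rescaling of the factors, so they are returned unscaled.

For each pairwise comparison, `nb_wald_test()` computes per-KO group means
of normalized counts, a pooled within-group method-of-moments dispersion
estimate (floored at 10⁻⁸ so degenerate KOs keep finite standard errors),
`log2FC = log2(m_T / m_B)`, a delta-method standard error, and a two-sided
p-value from the normal reference. When one group mean is exactly zero, a
pseudo-count of ½ is added to *both* group means — only then — which keeps
fold changes finite without biasing well-observed KOs and preserves the
sign symmetry that `extract_enriched_sets()` relies on. BH-adjusted
p-values below `alpha` (default 0.05) define the two directional
enriched-KO sets; their sizes are the *n* of the next stage.

This test is deliberately shrinkage-free: no empirical-Bayes dispersion
moderation, no outlier filtering. It is "DESeq2-like" in model but not in
numerics; the test suite checks that its fold-change estimates correlate
strongly with an independent NB implementation on simulated data, not that
they match bit for bit. With method-of-moments dispersions and a normal
reference the test is mildly anticonservative at very small group sizes;
its nominal behaviour is verified at 15 replicates per group in the suite,
and the planted-effect power checks use the experiment's own 5 replicates.

## Stage 2: pathway calls against a resampling null

For a directional enriched set of size *n* and a pathway with KO set *P*:

* **observed hits** = |enriched ∩ P|;
* **expected hits** = hits of a random *n*-subset of the universe (the
  collective predicted functional genome of the comparison: every KO with
  a nonzero count in at least one of its samples), redrawn `n_reps = 1000`
  times;
* the **difference of medians** = median(observed − expected draws);
* the **null distribution** repeats the procedure with the observed list
  *also* drawn at random: 1,000 differences between hit counts of two
  independent random *n*-subsets, sorted ascending; the 5% and 95% limits
  are the order statistics at ranks 50 and 950 (generalized to
  ⌈0.05·R⌉ and ⌊0.95·R⌋ for other replicate counts).

A pathway is *enriched* when its difference of medians lies strictly above
the upper limit, *depleted* strictly below the lower limit, otherwise not
significant — ties at a limit are not significant. Each draw is marginally
hypergeometric, and the null is deliberately the distribution of *single*
differences (not of medians of differences), which is the wider, more
conservative reading; both the replicate count and the limit ranks are
configurable through `bootstrap_config()`.

Implementation notes:

* Draws are true subset resampling (`sample.int` over universe indices),
  not parametric hypergeometric sampling; the enumerated hypergeometric
  pmf and an exhaustive enumeration of all subset pairs serve as
  independent oracles in the tests.
* Within one direction, each replicate's random subset is evaluated
  against all pathways at once via a sparse incidence-matrix product.
  Per-pathway marginals are exactly as if each pathway drew its own
  replicates; only the (never-used) cross-pathway joint distribution
  differs. This keeps 200 pathways × 1,000 replicates around a second.
* Every comparison/direction consumes an RNG substream derived from
  `(master seed, comparison id, direction)`, so adding a comparison never
  changes another's draws, and runs are byte-reproducible.
* Pathways with a single KO are legitimate (KEGG contains them) but are
  flagged (`size_one`) because one KO decides their call.
* An empty enriched set yields all-`not_significant` calls with a warning
  rather than an error, so a quiet comparison does not abort a run.

The **under-representation screen** (`underrepresentation_screen()`) runs
the same machinery once per dataset with the predicted metagenome's KO
list as the observed data and the full reference map as the universe;
pathways whose difference of medians falls below the 5% limit are present
in the reference mostly through KO redundancy, and are excluded from all
enrichment calls (they remain in the output, flagged
`excluded_by_screen`).

## Stage 3: the CSR trait registry

`load_trait_registry()` returns the frozen classification of KEGG pathways
into C, S and R classes, one conditional entry, and six foraging
pathways. Tallies are checked at load: 9 competitive, 6 stress-tolerant,
9 ruderal distinct traits, with the ABC-transporters entry conditionally
C or S (it counts toward S by default, the published tally; pass
`conditional = "C"` to resolve it the other way when the enriched
transporters are resource-acquisition systems).

Two curation decisions are frozen into the packaged file and worth
knowing:

* The ruderal columns of the published treatment table list ten distinct
  pathway names while the stated tally is nine. The registry keeps all
  ten names but maps "TCA cycle" to the trait "Carbon metabolism" (KEGG's
  carbon-metabolism overview pathway contains the citrate cycle), so
  every printed name classifies while distinct-trait tallies stay at
  nine.
* Entries whose provenance column reads `criteria-reconstructed` (the
  ninth competitive trait, biofilm formation, and the six foraging
  pathways) are stand-ins reconstructed from the published trait-definition
  criteria — the original curation table naming them was supplementary
  material that is not redistributed here. They are clearly flagged in
  the TSV; replace the file via `load_trait_registry(path)` if you carry
  your own curation.

`classify_calls()` maps treatment-direction enrichment calls to class-wise
*enriched* trait sets and baseline-direction enrichment calls to
class-wise *depleted* sets (a treatment's "decreased" traits). Matching is
case-insensitive and whitespace-normalized; called pathways missing from
the registry are reported under `unclassified`, never dropped silently. A
trait that would land in both sets through different pathway names
cancels out of both.

## Stage 4: CSR net-change scores

For each class X ∈ {C, S, R} with registry size N<sub>X</sub>:

delta_X = (enriched_X / N_X − depleted_X / N_X) × 100

Each axis is scaled by the number of traits in its own class
(N<sub>C</sub> = 9, N<sub>S</sub> = 6, N<sub>R</sub> = 9 under the default
conditional resolution); `denominator = "global"` scales all axes by the
24 CSR traits instead. Foraging and unclassified pathways never enter the
axes. Scores live in [−100, 100]; the baseline against itself is the
origin, and swapping enriched with depleted sets negates every delta. The
per-class default follows the axis-scaling statement accompanying the
published three-dimensional figure; the net (enriched − depleted) form is
the printed two-term equation.

## The synthetic-data generator

`generate_pathway_map()`, `study_design()`, `planted_effect()` and
`generate_counts()` produce complete synthetic inputs with known ground
truth, so every stage — and the whole chain — is testable without any
external download. Defaults mirror the study conditions the pipeline is
built for: the 2 × 3 factorial design at 5 replicates per cell, NB counts
with dispersion 0.1 around a base mean of 500, and pathway sizes from 1
to 30 KOs with a 0.2 chance of reusing an already-assigned KO, so the KO
redundancy that motivates the screen actually occurs in generated maps.
The sequencing-depth spread of real predicted tables is not documented
anywhere authoritative; the library-size coefficient of variation
defaults to 0.3, a mid-range value for amplicon libraries, drawn
log-normal and renormalized to geometric mean 1 so size-factor estimation
stays nontrivial but identifiable.

What the generator does *not* emulate, and what passing tests therefore
do not show about real data: correlated KOs within genomes (counts are
independent given the design), copy-number normalization artifacts,
compositionality of relative abundances, overdispersion heterogeneity
across KOs (a single α), or the phylogenetic structure of prediction
error. Recovery results on synthetic data are a check of internal
consistency, not a validation of PICRUSt predictions.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale simulations chosen
to finish in minutes while keeping Monte-Carlo error well inside the
asserted tolerances: null calibration pools 20 seeds × 200 pathways
(universe 2,000 KOs, n = 25); end-to-end recovery uses 40 pathways over
600 KOs, a planted 20-KO pathway at log2FC = 2 on half its KOs, and 20
seeds; oracle comparisons use populations of at most 12 KOs where exact
enumeration is feasible. Headline empirical rates under these conditions
(computed, not asserted): null enrichment-call rate ≈ 0.02 per pathway,
planted-pathway recovery 20/20 seeds, false pathway-call rate < 0.02.

Other numerical conventions: even-length medians use the midpoint;
dispersion estimates are floored at 10⁻⁸; enrichment requires strict
inequality against the limits; all seeds are explicit function arguments
and substreams are derived, never shared.

## Limitations

The classification is a frozen manual curation — there is no de-novo CSR
classifier here, and cell-wall related traits are deliberately absent from
the S class (non-canonical cell walls of common soil taxa confound them).
Scores depend on the choice of baseline community, which limits
cross-study comparability of absolute coordinates. The NB test's normal
reference is approximate at very small replicate counts; with the
experiment's 5 replicates per cell the enriched-KO sets it feeds forward
are somewhat liberal, which the pathway-level resampling null then
tolerates by construction (uniformly scattered false KO hits rarely
concentrate in one pathway).
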