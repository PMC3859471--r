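---
title: "Familial aggregation of a binary phenotype on population genealogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial aggregation of a binary phenotype on population genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famagg)
```

## The question and the design

Family clustering of a trait can come from shared genes, from shared
household environment, or both. Deep population genealogies allow a design
that ordinary family studies cannot: compare the relatedness of affected
individuals against matched controls across *all* degrees of relationship,
close and distant. Excess clustering among distant relatives — second
cousins, say — is hard to explain by shared lifestyle and points to genes.

`famagg` implements this design end to end for a binary low-BMI phenotype
(body mass index strictly below 18.5) observed on a multi-generation
genealogy with phenotype records available only for recent generations, the
situation created by linking a genealogy to driver's-license height/weight
data. The same machinery applies to any dichotomous trait on a pedigree
table.

## Data model and eligibility chain

A *pedigree* is a table of individuals with father/mother links, sex, birth
year, and a binary birthplace flag; a *phenotype table* carries BMI and the
record year (when several records exist per person, the most recent wins).
Every analysis restricts attention to individuals passing the
*genealogy-completeness filter*: both parents known, all four grandparents
known, and at least six of the eight great-grandparent slots known. This
mirrors the source study's eligibility chain (completeness, then a phenotype
record, then an optional age window, then the BMI threshold) and guarantees
that cases and controls have comparable quantity of genealogy data —
otherwise the relatedness comparison would be confounded by record depth.

## Pairwise relatedness

The *genetic distance* between two individuals is the minimal number of
meioses connecting them through a common ancestor (parent–offspring 1,
siblings 2, avunculars 3, first cousins 4, …). The *relatedness
coefficient* is `2^(-d)`: 0.50, 0.25, 0.125, 0.0625 along that ladder.

Two deliberate conventions:

* **Single shortest path.** Multiple common ancestors and inbreeding loops
  do not add contributions. The textbook kinship coefficient would give
  0.25 for parent–offspring and a multi-path sum would give 0.5 for full
  siblings through both parents; the convention used here reproduces the
  published coefficient ladder exactly and keeps the statistic
  interpretable as a function of the closest relationship.
* **Degree of relationship** is a different metric: the shortest path in
  the graph joining each individual to its parents, offspring, and full
  siblings. It is the literal closure of "second-degree relatives are the
  first-degree relatives of the first-degree relatives": grandparents and
  avunculars are second degree, first cousins and great-grandchildren third
  degree. Half-siblings are second degree because the sibling edge requires
  both parents shared. Note one consequence of taking the closure
  literally: a spouse sits at path length 2 through a shared child, so a
  handful of affines can enter distant buckets. In the deep, interconnected
  genealogies this package targets the effect is negligible (in our
  simulations >99% of bucketed individuals are blood relatives of a
  proband), and the relation-graph definition is kept because it is exactly
  testable against path enumeration.

Internally all pairwise quantities come from one pass that assigns every
individual its ancestor set with minimal meiotic depths; the distance of a
pair is the minimum summed depth over shared ancestors. This makes the
matched-control resampling (hundreds of set-level statistics per analysis)
cheap.

## The GIF and dGIF tests

For a member set of size `n`, the Genealogical Index of Familiality is the
mean relatedness coefficient over all `n(n-1)/2` unordered pairs, scaled by
100,000 — the classic display convention; the source publication never
states its scale, but its reported values are consistent with this one, and
the scale cancels in every comparison. The *distant* GIF (dGIF) keeps the
same denominator but counts only pairs at genetic distance ≥ 4 (first
cousins and beyond), so dGIF ≤ GIF always. The study text describes the
exclusion both as "first and second degree" and as "genetic distance < 4";
the two readings differ only for rare cross-generation pairs
(great-grandparent pairs have distance 3 but degree 3), and the
distance-based reading is the default with the threshold exposed as a
parameter.

Significance is empirical: 1,000 control sets (configurable) are drawn,
each matched to the cases by five-year birth-year bin, sex, and birthplace
flag, from the completeness-passing phenotyped pool. The p-value is the
fraction of control sets whose statistic is at least the case value — ties
count toward the tail, and a case statistic above every control is reported
as "<1/N" rather than zero. Matching uses a short relaxation ladder: exact
stratum first, then the birth-year bin widened by one bin on each side,
then a hard error naming the stratum (silent mismatching would quietly bias
the null). Control sets are drawn independently of each other, so an
individual may serve in many sets; within a set controls are distinct.

The *contribution curve* decomposes the GIF by distance — at distance `d`
the term is `#pairs(d) × 2^(-d) / #all pairs × scale` — and is the main
diagnostic plot: excess at small distances only suggests shared
environment; excess persisting at distance ≥ 4 supports a genetic
contribution.

## Cohort-standardized relative risks

All phenotyped individuals are assigned to cohorts by five-year birth bin ×
sex × birthplace, and the cohort rate is the phenotype prevalence within
the cohort. For each degree of relationship 1..7, the relatives of the
proband set are collected at their *minimal* degree (counted once each,
never as relatives of themselves, but a proband may be a countable relative
of another proband — without this, observed case counts among relatives of
an all-case proband set would be identically zero). Observed is the number
of cases among them; expected is the sum of cohort rates over them; RR =
observed/expected.

The interval on RR is the positivity-preserving log-scale ratio interval
`RR × exp(±z √(1/observed))` with expected treated as fixed; the published
intervals are consistent with this form (the variant is not stated in the
study; the first-degree upper bound reproduces exactly, the lower bound to
within one unit in the second decimal). The p-value is an exact Poisson
two-sided tail (twice the smaller tail, capped at 1); a two-sided normal
tail is exposed as an alternative since at least one published p-value
matches it slightly better. Prevalence tables use exact Clopper–Pearson
binomial intervals.

One behaviour of minimal-degree classification is worth knowing when
interpreting simulations: in a *dense* genealogy where most of the
population is phenotyped, distant relatives who are themselves
case-enriched tend to be "promoted" into close buckets (a case's cousin who
is also a case's sibling counts as first degree), which drains signal from
— and can even invert — the distant-degree RRs. The effect shrinks as the
phenotyped fraction of the genealogy falls and as probands are restricted
away from the highest-prevalence age bins, which is the regime of the real
driver's-license data; the signal-recovery suite therefore windows probands
to ages 25–64, as the source analysis did.

## High-risk pedigree scan

Clusters of related cases are anchored at founding couples (two spouses
both lacking recorded parents; single founders otherwise — anchoring at
single founders is available as an option). A cluster is the set of cases
descending from the anchor; clusters with fewer than two cases are
dropped, and any cluster whose case set is contained in another's is
removed, so no retained cluster is a subset of another while individuals
may appear in several. Each retained descendancy is then tested for excess:
observed cases among *all* phenotyped descendants versus the
cohort-standardized expectation, with a one-sided Poisson upper tail
`P(X ≥ observed)` — the study does not name its tail test, but its printed
example (18 observed vs 5.3 expected, p ≈ 1.1e-5) is consistent with this
choice to the precision its rounded expectation allows. High-risk pedigrees
are those with `p < 1e-4` and at least 10 observed cases, both
configurable.

## The synthetic population

No public data exist for the restricted genealogy this design was built
for, so the package ships a generator whose defaults are the study
conditions as far as they are stated, and field-plausible choices
elsewhere:

* **Structure.** Founder couples in generation 1; within-generation mating
  with full-sibling marriages excluded; Poisson(3) children per couple;
  each adult marries an immigrant founder-by-marriage (no recorded parents,
  born out of state) with probability 0.2 — chosen so that roughly 60% of
  recent-generation individuals pass the completeness filter, in the
  region of the real data's 1.19M-of-wider-population eligibility. Birth
  years are generation base + uniform jitter over a 25-year span; sex is a
  fair coin; in-genealogy births are in-state with probability 0.9.
* **Phenotype.** A liability-threshold model: `L = A + C + E` with
  additive variance `h²` (midparent transmission: founder `A ~ N(0, h²)`,
  child `A = (A_f + A_m)/2 + N(0, h²/2)`), sibship-shared environment
  `C ~ N(0, c²)` drawn once per parental couple, and residual
  `N(0, 1 − h² − c²)`, so `L` is marginally standard normal. The case
  threshold is the normal quantile of the age-bin target prevalence; the
  default prevalence map is the published U-shaped age profile
  (11% at 15–19 falling to 0.4% at 55–59 and rising again in old age).
  Defaults `h² = 0.6` (mid-range of twin-study BMI heritability estimates
  of 50–74%) and `c² = 0.1`. BMI is emitted as
  `18.5 − 3.8 × (L − threshold)`, a monotone decreasing transform anchored
  so `BMI < 18.5` exactly when the liability crosses the threshold; the
  slope only sets a plausible BMI spread (roughly 12–33) and affects no
  statistic.
* **Ascertainment.** Phenotype records exist only for the most recent
  `phenotyped_generations` (default 3) generations, with the reference
  year placed so those generations span ages ~15–90; earlier generations
  stay in the genealogy and contribute relatedness paths only.

What it does *not* emulate: mortality and migration schedules, assortative
mating, secular BMI trends across generations, reporting error in
self-reported height/weight, and incomplete phenotype coverage within the
recent generations (everyone recent is phenotyped). Passing tests therefore
show that the statistics behave correctly under a faithful liability-model
null and alternative — not that the generator reproduces the demographic
texture of any real population.

## Numerical and design choices

* Empirical p-values use the conservative ≥ tie rule and are reported with
  a display floor of `1/N` sets.
* Cohort and matching bins are `5 × floor(birth_year/5)`; every phenotyped
  individual with complete stratum attributes maps to exactly one cohort,
  and individuals missing an attribute are dropped with a counted warning.
* `expected = 0` with positive observed flags the RR as undefined rather
  than producing infinities; empty prevalence bins are flagged by `n = 0`.
* Degenerate inputs error early: GIF needs ≥ 2 members, control sampling
  refuses exhausted strata, self-pairs are undefined for distance and
  degree, and parentage cycles are reported with the offending ids.
* Determinism: every stochastic step takes an explicit seed; the simulator
  and control resampling restore the RNG state afterwards.

## Problem sizes used by the test suites

The packaged property suites run at sizes chosen to make Monte-Carlo
conclusions stable while keeping a full run of the suite around six
minutes on one core: oracle-equivalence checks on random pedigrees of ≤ 60
individuals; conservation checks over 200 random member sets; a null suite
(`h² = c² = 0`) of 20 replicates of ~5,000 phenotyped individuals with 200
control sets each, checking uniformity of the empirical GIF p-value,
coverage of the RR intervals, and emptiness of the high-risk scan at
`α = 1e-4`; and a signal-recovery suite (`h² = 0.6`) of 20 replicates of
~20,000 phenotyped individuals — the larger size gives the third-degree
expected counts (~50–70) needed to resolve the modest cousin-level
relative risk — checking that the GIF test rejects and the RR gradient
`RR₁ > RR₃ > 1` appears in at least 80% of replicates.

## Known limitations

* The single-shortest-path coefficient understates relatedness under
  inbreeding and double relationships by design; identity-by-descent under
  inbreeding (Karigl-style recursions) is out of scope.
* The relation-graph degree admits rare affine shortcuts, as discussed.
* Minimal-degree bucketing couples the degree strata (the promotion effect
  above); distant-degree RRs from dense, fully phenotyped genealogies
  should be read with that in mind.
* The matched-control null conditions on the realised case stratum
  composition; with very small strata the one-bin relaxation ladder can
  still fail, and it errors rather than mismatching.
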