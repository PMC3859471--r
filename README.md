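# famagg

Familial-aggregation analysis of a binary phenotype on deep population
genealogies: does a trait cluster in families, and does the clustering look
genetic or environmental?

`famagg` is aimed at genetic-epidemiology analyses of the kind run on
linked genealogy–records resources (a multi-generation pedigree joined to
administrative phenotype records such as driver's-license height/weight).
The worked phenotype is adult leanness — BMI strictly below 18.5 — but any
dichotomous trait on a pedigree works. Because such resources are
access-restricted, the package includes a liability-threshold population
simulator so every stage is runnable and testable out of the box.

## What it computes

* **Genealogical Index of Familiality (GIF).** For a case set, the mean
  pairwise relatedness coefficient `2^(-d)` (`d` = genetic distance in
  meioses: 1 parent/offspring, 2 siblings, 4 first cousins, …) over all
  unordered pairs, scaled by 10⁵. Significance is empirical, against the
  same statistic on sets of controls matched by birth-year bin, sex, and
  birthplace. The **dGIF** counts only pairs at distance ≥ 4, isolating
  distant relatedness that shared household environment cannot easily
  explain, and a contribution-by-distance curve shows where the clustering
  lives.
* **Relative risks in relatives.** Cohort-standardized RR = observed /
  expected cases among the 1st- through 7th-degree relatives of the case
  set, relatives counted once at their minimal degree; expected counts
  apply cohort-specific rates (5-year birth bin × sex × birthplace);
  log-scale ratio confidence intervals and exact two-sided Poisson
  p-values, plus exact Clopper–Pearson intervals for prevalence tables.
* **High-risk pedigrees.** Founder-couple-anchored clusters of related
  cases (maximal, no subset clusters), each descendancy tested for a
  case excess with a one-sided Poisson tail on observed vs
  cohort-expected counts.
* **Synthetic populations.** Generation-structured genealogies (founder
  couples, within-generation mating, immigrant spouses) with a familially
  correlated liability `L = A + C + E` (`h²` additive, `c²` sibling-shared)
  thresholded per age bin to a U-shaped prevalence profile, and phenotype
  records restricted to the most recent generations.

## Worked example

```r
library(famagg)

cfg <- sim_config(n_founder_couples = 150, n_generations = 6,
                  h2 = 0.6, c2 = 0.1)
pop <- simulate_population(cfg, seed = 42)
report <- run_pipeline(pop$pedigree, pop$phenotype,
                       run_config(n_control_sets = 200, seed = 42))
report
```

```
Familial-aggregation pipeline report
  individuals 13096, phenotyped 5819, cases 172 (window 58)
GIF analysis
  cases: 58, control sets: 200
  case GIF  265.44  (mean control 184.61)  empirical p 0.01
  case dGIF 159.57  (mean control 144.76)  empirical p 0.15
  high-risk pedigrees: 0
```

The 58 cases aged 25–64 are markedly more related to each other than 200
matched control sets are (GIF 265 vs 185, empirical p = 0.01): the
phenotype clusters in families. The dGIF (distance ≥ 4 pairs only) is
elevated but not significant at this sample size, so this particular run
cannot separate close-relative clustering from distant clustering.

```r
tidy(report$rr)
#>   degree n_relatives observed expected    rr ci_low ci_high  p_value
#> 1      1         252       34     8.41 4.04   2.89     5.66 5.42e-11
#> 2      2         380        9     7.62 1.18   0.614    2.27 7.10e- 1
#> 3      3         877       30    29.7  1.01   0.706    1.44 1   e+ 0
#> ...
```

First-degree relatives of cases carry four times the cohort-expected risk
(RR 4.04, CI 2.89–5.66); distant degrees sit near 1 in a population this
small — see the methods vignette (`vignettes/familial-aggregation.Rmd`)
for why dense, fully phenotyped genealogies attenuate distant-degree RRs
and how the calibration suites size their populations.

`autoplot(report$gif)` draws the case-vs-control contribution curve,
`autoplot(report$rr)` the RR-by-degree gradient, and
`run_pipeline(..., output_dir = "out")` writes a JSON report plus TSV
tables (prevalence, GIF curves, RR, pedigree scan). Files on disk use
tab-separated pedigree (`id father_id mother_id sex birth_year birthplace`,
`0` = missing parent) and phenotype (`id bmi record_year`, or
weight/height) formats via `read_pedigree()` / `read_phenotype()`.

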