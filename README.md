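# meptrace

Lineage-tree analytics and fate modeling for time-lapse-imaged hematopoietic
colonies.

Bipotent megakaryocytic–erythroid progenitors (MEPs) plated singly in
colony-forming-unit culture grow clones whose cells self-renew, commit to the
megakaryocytic (Mk) or erythroid (E) lineage, die, or terminally mature.
Long-term time-lapse imaging plus in-situ staining and supervised cell
tracking turn each colony into a rooted binary lineage tree with per-frame
positions and endpoint marker calls. `meptrace` consumes that tracking
output and quantifies the dynamics of self-renewal and lineage commitment:

* **Lineage reconstruction and fate inference** — parses track TSV and
  CTC-style lineage files into `lineage_tree` objects; labels every cell by
  back-propagating terminal lineage identity (CD41 → Mk; CD71-bright or
  CD235a → E; endomitosis → Mk), so a cell upstream of both lineages is
  called bipotent; classifies each bipotent division as expansion
  (1 MEP → 2 MEP), maintenance (1 MEP → 1 MEP + 1 committed daughter) or
  exhaustion (no bipotent daughter).
* **Kinetics** — per-generation death rates by state, expansion curves,
  division-outcome tables, commitment frequency, colony typing
  (Mk/E mixed, E-only, Mk-only, none) and colony-forming efficiency, plus
  t-test/ANOVA condition comparisons.
* **Motility** — per-cell total distance, diffusion distance,
  directionality and peak velocity on the non-uniform acquisition schedule.
* **Behavioral clustering** — PCA, Ward + silhouette selection of k,
  seeded k-means, and state-by-cluster enrichment tables.
* **Fate model** — the package core: a nonhomogeneous Markov model of
  division outcome versus generation,

  P(outcome j | from-state i, generation g) = softmax_j(α_ij + β_ij log g),

  with exhaustion absorbing, fitted by maximum likelihood (`mep_markov()`,
  an S3 model with `print`/`summary`/`coef`/`vcov`/`logLik`/`predict`/
  `simulate` methods), delta-method or bootstrap 95% intervals for 13
  generations, a likelihood-ratio test of homogeneity, and the expected
  first-division exhaustion under a uniform generational-age mixture.
* **Colony simulator** — a seeded generative twin (`synthetic_config()`,
  `generate_colonies()`, `generate_dataset()`) emitting track files and
  ground truth with the study's cycle times, death rates, commitment bias,
  marker-onset delays, motility ordering and acquisition schedule, plus
  `condition_variant()` for cytokine-withdrawal (−TPO / −EPO) cohorts.

## Worked example

Simulate a small control cohort, reconstruct and label it, and fit the fate
model:

```r
library(meptrace)
cfg <- synthetic_config(seed = 7, n_roots = 40, movie_hours = 200,
                        late_interval = 2, e_commit_max_gen = 3)
sim <- generate_colonies(cfg)
trees <- sim$trees

eff <- colony_efficiency(trees)
table(eff$calls)
#> MkE_mixed no_colony
#>        35         5
```

Thirty-five of 40 plated cells formed scoreable colonies (88%); 12% died
before producing progeny — in line with the configured 15.7% pre-division
death probability at this cohort size.

```r
fit <- mep_markov(division_events(trees), shared = TRUE)
fit
#> Nonhomogeneous Markov division-outcome model (from-state-independent)
#>   769 division events, logLik -917.645, 6 parameters, converged in 7 iterations
#>  any.maintenance_E.alpha   any.maintenance_E.beta any.maintenance_Mk.alpha
#>                  -1.3417                   1.3416                  -2.9013
#>  any.maintenance_Mk.beta     any.exhaustion.alpha      any.exhaustion.beta
#>                   1.6845                  -5.8034                   3.7141

subset(predict(fit, generations = c(1, 5, 9, 13)), outcome == "exhaustion")
#>    from_state generation    outcome      p   lo     hi
#> 4         any          1 exhaustion 0.0023 0.00 0.0047
#> 8         any          5 exhaustion 0.2254 0.19 0.2612
#> 12        any          9 exhaustion 0.5627 0.49 0.6338
#> 16        any         13 exhaustion 0.7569 0.67 0.8444

first_division_exhaustion(fit)
#> [1] 0.39
```

The positive `beta` coefficients say every non-expansion outcome gains on
expansion as generations pass; the exhaustion probability rises from under
1% at the first division to ~76% (95% CI 67–84%) by generation 13. If
plated cells were an equal mixture of generational ages 1–13, 39% would be
expected to exhaust at their first observed division — the model's
explanation for single-lineage colonies in static assays.

The motility, clustering and condition-comparison stages follow the same
pattern; see the methods vignette (`vignettes/mep-colony-analysis.Rmd`) for
the model, its assumptions and the design choices, and
`inst/scripts/meptrace.R` for a command-line wrapper
(`simulate` / `analyze` / `fit` / `cluster` / `compare`).

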