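# matekin

Pedigree kinship and inbreeding-avoidance analyses for plural-breeding
social groups.

In many cooperatively breeding mammals both sexes stay and breed in their
natal group, so potential mates range from non-relatives to full siblings.
`matekin` provides the full analysis pipeline for asking whether such animals
avoid inbreeding through kin-discriminating mate choice:

* **Pedigree machinery** — exact kinship `f(i,j)`, pairwise relatedness
  `r = 2f`, and inbreeding coefficients `F = f(dam, sire)` by the tabular
  recursion over a validated, topologically ordered pedigree, plus a Monte
  Carlo **gene-dropping** oracle (C++) for independent validation.
* **Constrained permutation tests** — are breeding pairs (mother × sire) or
  guard–female pairs less related than expected under random within-group
  pairing? Nulls preserve each female's number of distinct sires and, for
  guarding, every male's and female's number of links within an oestrus
  event. One-tailed Monte Carlo P with the add-one convention,
  `p = (1 + #{null ≤ obs}) / (n_perms + 1)`.
* **Inclusion filters with accounting** — the per-analysis criteria
  (parents confidently assigned, ≥ 80% of candidates assigned, within-group
  sire, natal-only variants) with per-criterion pass counts.
* **Mate-guard success GLMM and paired guard-vs-extra-pair comparisons** —
  binomial mixed model of whether a guard gained paternity; paired t-tests of
  a female's relatedness to her guard versus the extra-pair sire (overall and
  split by within-/extra-group).
* **Inbreeding-depression GLMMs** — yearling body mass (gaussian) and
  first-year survival (binomial) on F plus covariates, with backward
  elimination by likelihood-ratio tests at P < 0.05.
* **A forward-time population simulator** — groups, synchronous oestrus,
  mate-guarding, promiscuous paternity with tunable kin-avoidance
  (`exp(−beta·r)` choice weights), litters, survival and mass outcomes —
  emitting every canonical table, so the whole pipeline is verifiable
  without field data.

See the vignette (`vignettes/inbreeding-avoidance.Rmd`) for the models,
conventions and generator design.

## Worked example

Simulate a population in which both sexes avoid kin (guard-choice strength 2,
paternity-choice strength 4 on the `exp(−beta·r)` scale), then run the main
analyses:

```r
library(matekin)

sim <- simulate_population(sim_params(seed = 11, beta_guard = 2,
                                      beta_paternity = 4))
ds <- sim$dataset
A  <- relatedness_matrix(ds$pedigree)

fl <- breeding_pair_filter(ds, A)
fl$report
#> filter_report [breeding_pairs]: 793 input, 497 retained
#>   mother_parents_assigned      pass 691/793 (drop attribution 102)
#>   candidate_fathers_80pct      pass 617/793 (drop attribution 143)
#>   sire_within_group            pass 718/793 (drop attribution 51)

permutation_test(fl$dyads, ds, A, type = "breeding", n_perms = 10000,
                 seed = 12)
#> permutation_result [breeding]: observed mean r = 0.0749, null mean = 0.1289,
#>   one-tailed P = 9.999e-05 (497 dyads, 10000 permutations)

ep <- identify_epp(ds, A)
epp_comparison(ep$pairs, "all")
#> paired_test_result [all]: mean difference = 0.0355, t(214) = 3.095,
#>   two-tailed P = 0.002233 (n = 215)

fit_and_simplify(build_mass_frame(ds, inbreeding(ds$pedigree, A / 2)))
#> model_fit_result (gaussian, n = 2078)
#>          term   estimate      se chisq        p retained
#>             F -274.20000 94.0200  8.41 3.74e-03     TRUE
#>      age_days    1.58700  0.3707 18.23 1.96e-05     TRUE
#>  maternal_age    0.07988  0.2599  0.09 7.59e-01    FALSE
#>    group_size    1.38800  1.4660  0.88 3.48e-01    FALSE
#>        n_pups    0.21760  0.5888  0.14 7.12e-01    FALSE
#>  rainfall_30d    0.90780  4.0380  0.05 8.24e-01    FALSE
#>   intercept: 630.2 +/- 134.5
#>   random effects: group_id, attempt_id, dam_id, sire_id, individual_id
```

Reading the output: breeding pairs are substantially less related (mean
r = 0.075) than random within-group expectation (0.129) — the generated
avoidance is detected; unsuccessful mate-guards lose paternity to males less
related to the female than themselves (positive paired difference); and the
simulated inbreeding depression in yearling mass (true slope −347.9 g per
unit F) is recovered at −274 ± 94 g and retained by the backward
elimination, while the inert covariates are dropped.

The same analyses run from CSV files on disk (canonical headers, or a
`column_map` for foreign dialects) via `read_study_tables()`, and the whole
pipeline — data, kinship, filters, tests, models, JSON results and a Markdown
report — via `run_pipeline()`; a tiny example dataset ships under
`inst/extdata/example/`.

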