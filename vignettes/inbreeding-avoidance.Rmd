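---
title: "Pedigree-based inbreeding-avoidance analyses: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based inbreeding-avoidance analyses: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matekin)
```

`matekin` implements the statistical machinery used to ask whether members of
plural-breeding, philopatric social groups — groups in which both sexes stay
and breed alongside relatives, as in banded mongooses — avoid inbreeding by
kin-discriminating mate choice. Four questions structure the pipeline:

1. *Is inbreeding costly?* Mixed-model tests of inbreeding depression in
   yearling body mass and first-year survival.
2. *Are breeding pairs less related than random within-group pairs?*
   A constrained permutation test on mother–sire dyads.
3. *Do males direct mate-guarding at less related females?* A degree-preserving
   permutation test on guard–female dyads.
4. *Do females bias paternity away from related males?* A binomial GLMM of
   mate-guard success, and paired comparisons of a female's relatedness to her
   guard versus the extra-pair sire.

Everything runs on a pedigree plus five tabular inputs (group composition per
breeding attempt, attempt covariates, parentage assignments, guarding
observations, individual outcomes). A forward-time generator produces all of
these tables from known parameters, so every stage is testable without field
data.

## Pedigree quantities

Kinship `f(i,j)` is the probability that one allele drawn from `i` and one
from `j` are identical by descent. It is computed by the standard tabular
recursion over a topological ordering of the pedigree:

* `f(i,i) = (1 + f(dam_i, sire_i)) / 2`
* `f(i,j) = (f(dam_i, j) + f(sire_i, j)) / 2` for `j` ordered before `i`,

with unknown parents contributing 0. Pairwise relatedness is `r = 2 f` (the
numerator relationship), and an individual's inbreeding coefficient is the
kinship of its parents, `F_i = f(dam_i, sire_i)`.

Conventions, chosen once:

* **Founders** (records with no known parents) are non-inbred and mutually
  unrelated — the universal pedigree-analysis convention. Consequently `F = 0`
  whenever any parent is unknown.
* **A single unknown parent** is treated as a private founder: the recursion
  stays total and the `F = 0` rule falls out automatically. Parent ids that
  are referenced but have no record of their own are *promoted* to founder
  records (with a warning), so two offspring of the same unrecorded dam are
  still maternal half sibs.
* The full dense matrix is computed by dynamic programming rather than
  on-demand path counting: study populations of a few thousand individuals
  make the O(n²) table trivial, and downstream stages index pairs heavily.

`gene_drop()` is an independent Monte Carlo oracle for the recursion: every
founder receives two unique allele labels, each parent transmits one allele
uniformly at random per replicate, and F and r are estimated from label
matches. It is implemented in C++ (one pass per replicate over individuals
and pairs) and is used in the test suite to validate the recursion on random
multi-generation pedigrees to within Monte Carlo error.

## Constrained permutation nulls

Both randomization tests compare the observed mean pairwise relatedness of a
set of dyads against its distribution under constrained reshuffles, one-tailed
for *lower* relatedness than random:

* **Breeding dyads.** Each mother (per attempt) is reassigned to random adult
  males (aged > 365 days at oestrus start) from her group. A female with `k`
  distinct assigned sires in an attempt receives `k` *distinct* random males,
  sampled without replacement; males may be reused across females. Sampling
  without replacement mirrors the observed multiplicity of distinct sires
  (replacement policy is otherwise arbitrary). Dyads whose candidate pool is
  smaller than `k` are excluded from both the observed and the null sets and
  logged.
* **Guard dyads.** Within each oestrus event, guarded-female endpoints are
  permuted over guard slots, preserving each male's and each female's number
  of guarding links, with duplicate (male, female) edges forbidden. A uniform
  random permutation of the female multiset is drawn and rejected while
  invalid (cap 10 000), falling back to exhaustive enumeration for events of
  up to 8 links; a degenerate event keeps its observed edges. Because the
  multiplicity of index permutations per distinct valid configuration is
  constant, accepted draws are uniform over valid configurations.

The Monte Carlo P uses the add-one convention
`p = (1 + #{null ≤ observed}) / (n_perms + 1)`, so `p` is never 0, and ties
count as at least as extreme (the conservative choice). One known internal
inconsistency in this design's provenance — a retained dyad count quoted
differently for observed and permuted guard–female means — is resolved here
by always using a single retained set for both.

Inclusion filters reproduce the analysis-specific criteria (mother's parents
confidently assigned; ≥ 80% of candidate fathers, or of guarded females,
with assigned parents; within-group sire; "natal-only" variants restricted to
attempts where all relevant adults were born in the group). "Confidently
assigned" means both parentage confidences ≥ 0.8. Each filter reports
per-criterion pass counts and attributes every dropped row to the first
criterion it fails (reporting order only; retention is the conjunction). Two
genuinely open readings are exposed as arguments rather than decided
silently: the candidate-father denominator for the 80% rule
(`candidate_scope`, defaulting to within-group adult males so that criterion
and randomization pool coincide) and the maternal-age unit in the models
(`maternal_age_unit`, defaulting to months).

## Guard success and the paired comparison

A guard–female pair is *classifiable* when the female was confidently
assigned at least one offspring born 40–80 days after the observed oestrus
start; the guard is *successful* if any such offspring is his. Success is
modelled as a binomial GLMM with guard–female relatedness, male age rank,
female age, group sex ratio and guarding days as fixed effects, and social
group, attempt, guard and female identities as random intercepts.

For unsuccessful guards with exactly one distinct extra-pair sire (cases with
two or more distinct extra-pair identities are excluded — there is no unique
paired contrast), the paired t-test compares the female's relatedness to her
guard against her relatedness to the extra-pair male, overall and split by
within-group versus extra-group extra-pair sires. The t statistic is
`mean(d) / (sd(d)/√n)` on `n − 1` df; two-tailed P is reported (sidedness is
immaterial at the effect sizes of interest, and two-tailed is the
conservative default).

## Mixed models and the simplification procedure

All models are fitted with `lme4` by maximum likelihood (not REML), because
fixed effects are compared by likelihood-ratio tests and REML likelihoods are
not comparable across fixed-effect structures. `fit_and_simplify()`
implements the stepwise procedure: the least significant term (largest LRT p)
is dropped until every remaining term has P < 0.05; each eliminated term is
then returned individually to the minimal model to report its effect size
and its chi-square against the minimal model. Singular random-effect fits are
reported with a flag rather than silently refitted; non-convergence halts
simplification with a partial result. Likelihood-ratio chi-squares are
clamped at 0 (optimizer noise can make nested log-likelihoods cross by tiny
amounts).

## The synthetic population generator

`simulate_population()` emulates the study design generatively:

* Several social groups founded by unrelated adults of both sexes; all
  offspring are philopatric, so relatedness accumulates within groups over
  time while remaining variable (founder lineages persist).
* Per group and ~91-day breeding attempt: adult females enter oestrus
  synchronously with probability 0.7 each (giving the observed 1–10 oestrous
  females); each receives 1 + Poisson(0.4) guards; litters are Poisson with
  mean 3; births fall 60 days after oestrus, inside the 40–80-day attribution
  window.
* Guard choice weights adult males by `exp(−beta_guard · r)`; sire choice
  weights by `exp(−beta_pat · r)` with a multiplicative boost for the
  principal guard calibrated so his baseline per-litter paternity share is
  0.3 (reproducing a ~1/3 observed guard success rate), and a 0.1 probability
  per fresh draw that the sire is extra-group. The exponential kernel is the
  simplest monotone avoidance weight, and `beta = 0` recovers *exact* random
  mating — required for the type-I-error tests. Both betas default to 0:
  avoidance is the treatment, not the baseline.
* Within-litter paternity is concentrated: each later pup reuses the previous
  pup's sire with probability 0.75. Without this, almost every unsuccessful
  guard faces two or more distinct extra-pair sires and the paired comparison
  starves, which contradicts the sampling structure the pipeline is built
  for (single-extra-pair-identity cases dominating).
* Outcomes: survival to 1 year is Bernoulli on a logit scale (intercept
  −1.31, rainfall slope 0.20 per mm, F slope `gamma_survival`, default
  −0.03); survivors get yearling mass records at 350–370 days
  (intercept 807.5 g, 1.15 g/day age slope, F slope `gamma_mass`, default
  −347.9 g) with group/attempt/mother/father/individual random effects and
  90 g residual SD. These defaults are the effect sizes under study, so a
  default simulation carries a detectable mass signal and a null survival
  signal.
* Demographic balance: adults die with probability 0.07 per attempt interval
  and groups are capped at 24 adults (random departures), keeping group sizes
  in the realistic 5–30 range instead of growing geometrically.
* A **burn-in** of 8 pre-observation attempts per group runs the identical
  breeding process but emits only pedigree and parentage rows (attempt
  unknown), no behavioural tables. This mirrors a study whose observation
  window sits on top of a deeper multi-generation pedigree; without it, the
  "80% of candidates with assigned parents" criteria exclude most early
  attempts because founders dominate the rosters.

What the generator does **not** emulate: group fission and eviction cohorts,
immigration between established groups, territory or predation dynamics,
genotyping and parentage-assignment error (assignment confidence defaults to
1), seasonal rainfall structure, or age-dependent fecundity. Passing tests on
this generator therefore demonstrate the *statistical machinery* —
calibration, power, parameter recovery — not robustness to those field
realities.

## Numerical and testing choices

* Every stage draws from an explicit integer seed; pipeline stages derive
  independent substream seeds from the config seed by hashing the stage name,
  so results are reproducible and stages are insensitive to execution order.
  Fixed seed implies byte-identical output tables and JSON.
* Test problem sizes: the gene-dropping validation uses 100 000 replicates on
  twenty ~60-individual, 5-generation pedigrees; calibration of the
  randomization test uses 200 replicate populations (6 groups × 12 observed
  attempts) per avoidance strength with 300 permutations per test (p
  resolution 1/301 — ample at the 0.05 level); parameter recovery uses 100
  replicates of ~800 yearling mass records. These sizes make the full suite
  run in tens of minutes on one core while keeping binomial/KS slack small.
* Dates are ISO-8601; ages are derived at event dates; individuals of unknown
  age are excluded from age-dependent rules (adult = age > 365 days).

## Limitations

* The pipeline *consumes* a pedigree; pedigree inference, genotyping and
  assignment-bias analysis are out of scope.
* Relatedness between an individual with assigned parents and a founder
  reflects the founder conventions; the inclusion filters are designed to
  keep such pairs out of the tested dyads, but matrices returned by
  `relatedness_matrix()` contain them.
* With marker data absent, assignment confidences are taken at face value
  from the parentage table.
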