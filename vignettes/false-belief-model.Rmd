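---
title: "A causal Bayesian network model of children's false belief reasoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A causal Bayesian network model of children's false belief reasoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomnet)
```

## The problem and the model

In the unexpected-contents false-belief task a child first discovers that a
familiar container (say, a Band-Aid box) holds something surprising (a toy),
and is then asked what a naive agent — who has never seen inside — thinks the
box contains. Answering "Band-Aids" requires attributing to the agent a
belief that contradicts what the child knows to be true. Developmental
theory-of-mind (ToM) scales place this ability after two earlier
achievements: understanding that people can hold *diverse beliefs* (DB) about
the same situation, and understanding that perceptual *knowledge access* (KA)
determines what someone knows.

`tomnet` models the reasoning behind this task as inference in a five-node
causal Bayesian network. The world state $W$ is fixed (the box holds the
toy). The child's own visual access $V_S$ is observed evidence, always 1:
the task protocol guarantees the child saw the contents. Three binary latent
variables remain: the child's own belief $B_S$, the other's visual access
$V_O$, and the other's belief $B_O$ (belief variables code 1 for the true
belief, 0 for the false/default belief; access codes 1 for "contents
observed"). The joint factorises along the causal arrows as

$$P(V_O, B_O, V_S, B_S, W) = P(B_O \mid V_O, B_S, W)\, P(V_O \mid V_S)\,
P(B_S \mid V_S, W)\, P(V_S)\, P(W).$$

Because every quantity of interest conditions on $V_S = 1$ and the constant
$W$, the package treats $P(V_S)$ and $P(W)$ as unit factors throughout; they
are never parameterised. Four probabilities specify the rest:

| parameter | default role | meaning |
|---|---|---|
| $\pi_B$ | free, $[0,1]$ | degree of attributing *different* beliefs to others; gates the theory-based strategy |
| $\pi_V$ | free, $[0,1]$ | degree of correctly identifying the other's visual access |
| $\delta$ | small | probability of failing to maintain one's own updated belief (memory slip) |
| $\epsilon$ | small | attributed chance that the other expects non-default contents |

The self-belief and other-access tables are
$P(B_S = 0 \mid V_S = 1, W) = \delta$ and
$P(V_O = 0 \mid V_S = 1) = \pi_V$ (with probability $1 - \pi_V$ the child
mistakenly projects their own access onto the other). The key table is a
mixture gated by $\pi_B$:

$$P(B_O \mid V_O, B_S, W) = \pi_B\, P(B_O \mid V_O, W) +
(1 - \pi_B)\, P(B_O \mid B_S),$$

whose first component runs the internal model of the *other*
($P(B_O = 0 \mid V_O = 1, W) = \delta$,
$P(B_O = 0 \mid V_O = 0, W) = 1 - \epsilon$) — theory-based reasoning — and
whose second copies the child's own belief deterministically onto the other —
simulation-based reasoning under a true-belief default. `build_cpts()`
materialises all three tables explicitly (including the redundant
$P(\cdot = 1)$ rows, so normalisation is a testable property rather than an
identity by construction), and `enumerate_joint()` exposes the full joint
over the eight latent assignments.

Marginalising $V_O$ and $B_S$ yields the probability of a correct
false-belief answer,

$$\pi_{FB} = P(B_O = 0 \mid V_S = 1, W)
= \pi_B \pi_V (1 - \epsilon) + (1 - \pi_B \pi_V)\, \delta,$$

which `predict_false_belief()` computes either by this closed form or by
explicit enumeration; the two routes agree to machine precision and the
enumeration path exists purely as an independent check on the algebra.
`strategy_decomposition()` splits the same quantity into the theory term
$\pi_B[\pi_V(1-\epsilon) + (1-\pi_V)\delta]$ and the simulation term
$(1-\pi_B)\delta$.

With both noise terms small, $\pi_{FB} \approx \pi_B \pi_V$
(`approximate_false_belief()`). The error of this product approximation is
the signed convex-type combination
$(1 - \pi_B\pi_V)\delta - \pi_B\pi_V\,\epsilon$, so its magnitude never
exceeds $\max(\delta, \epsilon)$ — an exact bound the test suite checks over
the whole parameter hypercube. The relation is *bilinear*: at zero noise
$\pi_{FB}$ is exactly linear in $\pi_B$ with slope $\pi_V$ and vice versa,
and it is non-decreasing in both abilities whenever $\delta + \epsilon < 1$.

## Mapping to ToM-scale data and the likelihood

In ToM-scale studies, $\pi_B$ corresponds to a group's proportion correct on
the diverse-beliefs task, $\pi_V$ on the knowledge-access task, and
$\pi_{FB}$ on the unexpected-contents false-belief task. `tomnet` treats a
group's per-task counts as independent binomials,

$$k_{DB} \sim \mathrm{Bin}(n_{DB}, \pi_B), \quad
k_{KA} \sim \mathrm{Bin}(n_{KA}, \pi_V), \quad
k_{FB} \sim \mathrm{Bin}(n_{FB}, \pi_{FB}),$$

where $\pi_{FB}$ inside the likelihood is always the full closed form, never
the product approximation (the approximation is a derived insight, not the
model). Boundary probabilities are handled exactly ($0 \log 0 := 0$), so a
likelihood of $-\infty$ is a legal value distinct from a validation error.

Priors are independent betas (`tom_priors()`). Defaults: $\mathrm{Beta}(1,
19)$ on $\delta$ and $\epsilon$ — mode 0, mean 0.05, matching the task
protocol's control questions that make large memory slips and non-default
expectations rare — and flat $\mathrm{Beta}(1, 1)$ on $\pi_B$ and $\pi_V$.
These are declared choices, exposed rather than hidden: every shape is
overridable, and the reported fits should be read conditional on them.

## Estimation: multistart MAP and the grid oracle

`fit_map()` maximises the log posterior over $(0,1)^4$ on the logit scale
(an unconstrained, smooth one-to-one transform) with BFGS and an analytic
gradient, from a fixed start set: an empirical plug-in point (clipped
observed DB/KA proportions, noise at the prior mean) plus Halton
low-discrepancy points (abilities spread over $(0.02, 0.98)$, noise over
$(0.005, 0.295)$, the region where its posterior mass lives). Ten restarts
by default, relative objective tolerance $10^{-8}$, at most 500 iterations
each. Because the start set is fixed, fitting is fully deterministic — a
rerun with the same data and configuration is byte-identical, which the test
suite asserts on the serialised reports. Estimates within $10^{-4}$ of 0 or
1 are flagged as boundary solutions; with mode-zero noise priors and data
consistent with the product relation, $\delta$ and $\epsilon$ legitimately
sit at 0 and are reported as such.

`fit_map_grid()` is the independent oracle: an exhaustive evaluation of the
log posterior on a lattice (defaults: step 0.01 for $\pi_B, \pi_V$ over
$[0,1]$; step 0.005 for $\delta, \epsilon$ over $[0, 0.25]$, where the
mode-zero priors concentrate the noise mass), with ties broken towards the
lexicographically smallest $(\delta, \epsilon, \pi_B, \pi_V)$ —
deterministic and documented. On every test dataset the optimiser's log
posterior dominates the grid's (it is a continuous optimum) and the two
agree within one grid step in the ability coordinates.

### Partial identifiability of the noise parameters

The three observed proportions inform four parameters, and the FB likelihood
constrains $\delta$ and $\epsilon$ only through the single combination
$q(1-\epsilon) + (1-q)\delta$ with $q = \pi_B \pi_V$. The orthogonal
direction is identified solely by the priors, which are nearly linear on it
— a soft ridge. One practical consequence, verified numerically and worth
knowing when comparing estimators: the lattice argmax of `fit_map_grid()`
can compensate the quantisation of $q$ (pi-step 0.01) through the noise
coordinates with leverage $1/(1-q)$, so its $\delta$ or $\epsilon$ can sit
two to three noise-grid steps (up to $\approx 0.015$) from the continuous
MAP even though both procedures are exactly correct on their own domains,
and the posterior difference involved is a few hundredths of a log unit.
The offset scales with the pi grid step, not with the cohort size. The
ability estimates $\pi_B, \pi_V$ — the scientifically interpreted quantities
— do not suffer from this: they agree within one grid step throughout the
test suite. Fitted $\pi_{FB}$ is likewise stable, since it is the identified
combination itself.

## The synthetic-data generator

No behavioural counts are shipped: the bundled fixture
(`inst/extdata/tom_scale_synthetic.csv`) and all test data are generated by
the package's own sampling module, so every number in the repository is
reproducible from code and documented true parameters.

`sample_network()` draws ancestral samples of the network ($B_S$, then
$V_O$, then $B_O$ from the mixture table) under the fixed evidence
$V_S = 1$. `simulate_study_counts()` emulates a cohort of children whose
per-task responses are independent Bernoulli trials with success
probabilities $\pi_B$, $\pi_V$, $\pi_{FB}$; per-task draws come from
sub-streams split from the seed, so adding a task never perturbs earlier
draws, and `simulate_study_table()` splits per-group sub-seeds the same way.

The fixture emulates a developmental cross-section of six cohorts of 80
children per task (typical ToM-scale cohort sizes are a few dozen per
group), generated with seed 20160 from:

| group | $\pi_B$ | $\pi_V$ | $\delta$ | $\epsilon$ |
|---|---|---|---|---|
| age3 | 0.55 | 0.50 | 0.02 | 0.02 |
| age4 | 0.70 | 0.65 | 0.02 | 0.02 |
| age5 | 0.85 | 0.80 | 0.02 | 0.02 |
| age6 | 0.95 | 0.90 | 0.02 | 0.02 |
| western_preschool | 0.85 | 0.75 | 0.02 | 0.02 |
| eastern_preschool | 0.70 | 0.85 | 0.02 | 0.02 |

The last two rows mirror the cross-cultural contrast in task difficulty
ordering (DB before KA for Western children, KA before DB for Asian/Middle
Eastern children); the model predicts — via the symmetry of
$\pi_B \pi_V$ — that this ordering is irrelevant to false-belief level, and
the fits reproduce that.

What the generator deliberately does *not* emulate: within-child correlation
across tasks (the model's own independence assumption; real cohorts may
violate it), age-graded longitudinal drift within a group, practice or
ordering effects, and item-level variation. Passing tests therefore show
that the pipeline recovers the model's parameters *when the model is true* —
parameter recovery and internal consistency — not that the model is correct
for any particular empirical population.

```{r example, fig.width = 7, fig.height = 4}
table <- read_study_table(system.file("extdata", "tom_scale_synthetic.csv",
                                      package = "tomnet"))
report <- fit_study_table(table)
report$correlation
autoplot(report)
```

## Numerical choices and degenerate inputs

* Parameter validation accepts the closed interval $[0,1]$ (limiting cases
  are meaningful); `NA`/`NaN` and out-of-range values raise classed errors
  naming the offending field.
* On the logit scale, probabilities are clamped to
  $[10^{-12}, 1 - 10^{-12}]$ inside the optimiser so the chain-rule factor
  $p(1-p)$ cannot produce `NaN` gradients when a restart wanders far out;
  non-finite objectives are replaced by a large penalty.
* The internal optimiser objective is algebraically identical to
  `log_posterior()`; a property test asserts equality on random interior
  points and checks the analytic gradient against central differences.
* Grid tie-breaking is lexicographic in $(\delta, \epsilon, \pi_B, \pi_V)$,
  smallest first; a single-point grid returns that point.
* `read_study_table()` enforces the exact header and distinguishes parse,
  schema, and integrity errors by condition class, with row numbers.
* Degenerate counts ($k = 0$ or $k = n$) are legal; the MAP may then sit on
  the boundary and is reported as-is with a boundary flag.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 1000 uniform parameter
quadruples for the closed-form/enumeration, decomposition, and
approximation-bound properties; 100,000 ancestral draws for Monte-Carlo
convergence (three binomial standard errors); 100 replicate cohorts of 2,000
children per task for parameter recovery (mean bias within $\pm 0.01$, RMSE
$\le 0.02$ on $\pi_B, \pi_V$); 20 simulated datasets for the optimizer/grid
cross-validation; and the six-group fixture-scale study (80 children per
task) for the end-to-end workflow, where the observed-vs-fitted correlation
across all 18 group × task cells is about 0.98.

## Known limitations

* The network is specific to the unexpected-contents task. The
  change-of-location task needs additional desire/action structure and is
  out of scope, as are diverse-desires data and scalogram analyses.
* Only MAP point estimates are produced — no MCMC, credible intervals, or
  model comparison. The partial identifiability above means interval
  statements about $\delta$ and $\epsilon$ separately would be mostly
  prior-driven anyway.
* Groups are fitted independently on aggregated counts; there is no
  hierarchical pooling across groups or ages, and no individual-level
  modelling.
* The prior hyperparameters are package defaults with the stated qualitative
  shape (small noise favoured); conclusions about $\delta$ and $\epsilon$
  should be checked for sensitivity to them via `tom_priors()`.
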