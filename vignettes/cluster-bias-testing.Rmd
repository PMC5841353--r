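---
title: "Testing items for cluster bias in two-level factor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing items for cluster bias in two-level factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterbias)
```

## The model

`clusterbias` works with balanced two-level data: `G` clusters (teams,
classrooms, countries) of a common size `n`, each member scored on `p`
continuous items assumed to reflect one latent factor at each level. The
total covariance of the items decomposes into independent within-cluster
and between-cluster parts,

$$\Sigma_T = \Sigma_W + \Sigma_B,$$

and the one-factor measurement structure restricts each part to

$$\Sigma_W = \Lambda_W \phi_W \Lambda_W' + \Theta_W, \qquad
  \Sigma_B = \Lambda_B \phi_B \Lambda_B' + \Theta_B,$$

with loading vectors $\Lambda_W, \Lambda_B$, scalar factor variances
$\phi_W, \phi_B$, and diagonal residual matrices $\Theta_W, \Theta_B$.

*Cluster bias* is level-2 measurement non-invariance: when loadings are
equated across levels, bias in an item surfaces as non-zero between-level
residual variance for that item. An item is free of cluster bias when its
loading is equal across levels **and** its between residual variance is
zero — two constraints, hence the 2-df tests below.

## Estimation

For balanced data the normal log-likelihood depends on the data only
through the pooled within-cluster SSCP matrix $A$ and the cluster means.
The stacked $np$-vector of one cluster has covariance
$I_n \otimes \Sigma_W + J_n \otimes \Sigma_B$, which yields

$$-2\log L = Np\log(2\pi) + (N-G)\log|\Sigma_W| +
  \operatorname{tr}(\Sigma_W^{-1}A) + G\log|\Sigma_W + n\Sigma_B| +
  n\sum_g (\bar y_g-\mu)'(\Sigma_W + n\Sigma_B)^{-1}(\bar y_g-\mu).$$

Item means are saturated and never constrained, so $\mu$ is profiled out
analytically at its MLE, the grand mean; the optimizer only ever sees
covariance parameters. The test suite verifies this expression against a
brute-force evaluation that literally stacks each cluster and computes the
multivariate-normal density — to eight significant digits — so every
likelihood-ratio statistic downstream inherits that accuracy.

`mlcfa()` minimizes this function by BFGS with an analytic gradient, on
*raw* parameters. Design choices that matter:

* **No robust (sandwich) machinery.** Point estimates and log-likelihoods
  under normal-theory ML are exactly what the unscaled $-2\log L$
  difference test consumes; robust corrections would change standard
  errors, which nothing here uses.
* **Heywood cases are allowed.** Variances are not reparameterized to be
  positive, so a negative variance estimate can and does occur; the fit is
  then flagged inadmissible (`is_admissible()`) but is still used for the
  test, mirroring common practice in simulation bookkeeping. Points where
  an implied matrix loses positive definiteness are returned to the line
  search as infinitely bad, which keeps iterates in the evaluable region
  without constraining the solution.
* **Starts and restarts.** Starting values come from the sufficient
  statistics (loadings at 1, $\Theta_W$ at half the pooled-within
  diagonal, $\phi_W$ at half its mean off-diagonal with a 0.05 floor,
  $\phi_B$ from the method-of-moments between matrix with a 0.01 floor,
  free $\Theta_B$ entries at 0.01). On failure up to five multiplicative
  log-normal jitters (sd 0.3) are tried and the best converged solution
  wins; if everything fails, a non-converged `FitResult` is returned and
  counted, never thrown.
* **Convergence.** Relative change in $-2\log L$ below `1e-10` with an
  iteration cap of 2000. Tight tolerances matter here: a sloppy optimum in
  either member of a nested pair shows up directly as a spurious negative
  likelihood-ratio statistic.
* **Balanced designs only.** The likelihood above is exact for balanced
  data; unbalanced input is rejected rather than silently approximated.

## The two testing strategies

Both strategies test, for one item at a time, the same two constraints —
the item's cross-level loading equality and a zero between residual
variance — with an unscaled likelihood-ratio statistic
$2(\ell_0 - \ell_1)$ referred to $\chi^2_2$ (for which the upper tail has
the closed form $e^{-LRT/2}$, a handy numerical cross-check). They differ
in the baseline:

* **Free baseline** (`strategy = "free"`): the unrestricted model carries
  only identification constraints — the referent item's loading fixed at 1
  at both levels — and the restricted model adds the tested item's two
  constraints.
* **Constrained baseline** (`strategy = "constrained"`): the baseline is
  the cluster-invariance model (all loadings equated across levels, all
  between residual variances zero) and the comparison model frees the
  tested item's two parameters, all other items keeping their
  constraints. Tests of further items always revert to the original
  baseline; nothing is carried over.

Outcomes follow a four-way taxonomy: `significant`, `non_significant`,
`inconclusive_negative` (a negative statistic — possible in practice when
either optimum is imperfect, and never clipped to zero), and
`non_converged`. Only `significant` flags an item as biased.

Two open points had to be settled:

* **The referent's own between residual variance** is *free* in the
  free-baseline models. The free baseline is defined by carrying only
  identification constraints, and fixing that variance is not needed for
  identification with five indicators. A sensitivity switch
  (`referent_theta_b = "zero"`) implements the other reading; the 2-df
  bookkeeping is unaffected either way.
* **The constrained-baseline comparison frees both parameters at once**
  (2 df), not the residual variance alone (1 df), so that the two
  strategies test the same hypothesis. The 1-df residual-only variant is
  deliberately not the default and is out of scope here.
* $\alpha = 0.05$ throughout, with no multiple-testing correction across
  items: items are tested one at a time against the original baseline and
  per-item rates are reported.

## The simulator

`simulate_condition()` generates data from the crossed design the package
is built to study: cluster sizes $n \in \{2, 5, 25\}$, cluster counts
$G \in \{50, 100\}$, intraclass correlations $\{0.10, 0.20, 0.30\}$, 0–2
biased items at 1% or 5% bias, and a biased or unbiased referent. The
generating model has one within factor with variance 1, all loadings 1 at
both levels, zero between residual variances, and item scores

$$y_{gji} = \eta_{B,g} + c_i V_g + \eta_{W,gj} + \varepsilon_{gji},$$

where $V_g \sim N(0,1)$ is a cluster-level *violator* variable with a
direct effect $c_i$ on each biased item — the restricted-factor
construction of uniform bias. Two closed forms pin the design down:

* the between factor variance that makes every unbiased item's ICC hit
  its target exactly,
  $\phi_B = \mathrm{icc}(\phi_W + \theta_W)/(1 - \mathrm{icc})$;
* the violator effect sized against the *base* total variance (without
  $V$'s own contribution),
  $c = \sqrt{\mathrm{bias\_pct}\,(\phi_B + \phi_W + \theta_W)}$, so a "5%
  biased" item really carries 5% more total variance than its unbiased
  peers.

Choices made once and not revisited:

* **$\theta_W = 0.5$ per item** (within-level item reliability 2/3, a
  mid-range value for short survey scales). The design is parameterized in
  $\theta_W$ throughout and the generator exposes it (`theta_w`), since
  the ICC and bias algebra — not any particular residual value — is what
  defines the conditions.
* **One shared violator** loads on all biased items of a condition rather
  than one violator per item. A shared $V$ induces between-level residual
  *covariance* $c_i c_j$ between biased items, which none of the fitted
  models (all diagonal $\Theta_B$) can absorb — exactly the
  misspecification regime the two strategies are meant to cope with. The
  test suite verifies this induced covariance empirically.
* **Seeding** is stream-based: each replication's seed derives from the
  (master seed, cell id, replication index) triple, so any cell can be
  regenerated independently and grids are parallelizable and resumable.

What the generator does *not* emulate: non-normal or ordered-categorical
responses, unequal cluster sizes, intercept shifts as an explicit bias
mechanism, and missing data. Passing tests therefore speak to decision
accuracy under clean multivariate-normal conditions, not to robustness
against those complications.

## The Monte Carlo harness

`run_cell()` runs one condition: per replication it simulates a dataset,
fits each strategy's baseline once, tests the true-positive target item
(item 2, or item 4 when item 2 is the biased referent) and the
false-positive target (item 3), and tallies
flagged / non-significant / negative-LRT / non-converged outcomes. The
same datasets are analyzed under both strategies. Rates divide by the
*intended* replication count, so lost runs lower the rates rather than
shrinking the denominator, and the accounting identity
`flagged + non-significant + NLD + non-converged = intended` is asserted
per cell. `run_grid()` stacks cells (18 zero-bias baseline-check
conditions plus 144 bias conditions in the full design),
`aggregate_overall()` averages cell rates unweighted (the design is
balanced), and `eta_squared()` decomposes cell-level rates into ANOVA
effect shares, cells as observations.

## Problem sizes used in the checks

The packaged checks scale the study to desk size while keeping every
condition intact: the two saturated-power cells and the zero-bias
calibration cells run at the full 500 replications; the two 72-cell bias
grids behind the overall-rate and direction checks run at 40 replications
per cell (the acceptance script uses 50), where the per-cell Monte Carlo
standard error of ~0.08 averages down to under 0.01 on 72-cell
aggregates; estimator calibration uses 200 replications at
$G = 500, n = 25$. Single cells at full replication counts are a
one-line `run_cell()` call away.

## Known limitations

* Only the one-factor-per-level, five-ish-item, balanced design family is
  supported; multi-factor structures and discrete-group invariance
  modeling are out of scope.
* Non-convergence and negative-LRT *frequencies* depend on optimizer
  internals; different software recreates them only qualitatively, so
  they are reported as tallies, not matched to any external count.
* No standard errors are computed — nothing in the testing procedures
  needs them — so `vcov()`-style inference on individual parameters is
  deliberately absent.
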