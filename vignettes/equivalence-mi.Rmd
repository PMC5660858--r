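---
title: "Measurement invariance by equivalence testing and projection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement invariance by equivalence testing and projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equivMI)
```

This vignette documents the statistical model behind **equivMI**, the
choices the package makes where the methodology leaves room, and what
its tests do and do not establish.

## 1. The multi-group factor model and the invariance sequence

For groups $j = 1,\dots,m$ with $p$ manifest variables and $k$ factors,

$$x^{(j)} = \gamma^{(j)} + \Lambda^{(j)} \xi^{(j)} + \varepsilon^{(j)},$$

with $E(\xi^{(j)}) = \tau^{(j)}$, $\mathrm{Cov}(\xi^{(j)}) =
\Phi^{(j)}$, and diagonal $\mathrm{Cov}(\varepsilon^{(j)}) =
\Psi^{(j)}$, so that $\mu^{(j)} = \gamma^{(j)} + \Lambda^{(j)}
\tau^{(j)}$ and $\Sigma^{(j)} = \Lambda^{(j)} \Phi^{(j)}
\Lambda^{(j)\prime} + \Psi^{(j)}$.

Estimation is normal-theory ML on summary moments. The discrepancy is
the sample-size-weighted
$F_{ml} = \sum_j (n_j/N) F_j$ with
$F_j = \log|\Sigma_j| - \log|S_j| + \mathrm{tr}(S_j \Sigma_j^{-1}) - p
+ (\bar x_j - \mu_j)' \Sigma_j^{-1} (\bar x_j - \mu_j)$,
and the test statistic is $T_{ml} = (N - m) F_{ml}$. The alternative
$\sum_j n_j F_j = N\,F_{ml}$ convention used by some packages is
available via `tstat = "sum"`; the equivalence-testing calculus below
assumes the $(N-m)$ scale, which is why it is the default. Per-group
configural rows are single-group fits on the same convention,
$T = (n_j - 1) F_j$.

`run_mi_sequence()` fits, in order: configural per group, configural
combined, metric ($\Lambda$ equal), equal error variances, equal
factor covariances, scalar ($\gamma$ equal), equal latent means,
strict (scalar + equal $\Psi$), strict + equal means. Difference
statistics are taken against the nesting parent of each step (metric
vs combined configural; residuals and scalar vs metric; varfactor vs
residuals; strong.means and strict.residuals vs scalar; strict.means
vs strict.residuals). The test of equal population covariance matrices
$H_\sigma$ has the closed-form likelihood-ratio solution
$\hat\Sigma = \sum_j (n_j/N) S_j$ under saturated means, so
`cov_equality_test()` computes it without iteration. (The originating
software describes a Lagrange-multiplier version; the LR form is fully
determined by the model, has identical df $(m-1)p(p+1)/2$, and is
asymptotically equivalent.)

**Identification.** The first indicator of each factor is the marker
(loading fixed at 1); factor variances are free; intercepts are free
(latent means fixed at 0, i.e. saturated means) until intercepts are
constrained equal, after which $\tau^{(1)} = 0$ and the other groups'
latent means are free. For the canonical 2-group, 3-factor,
6-indicator model this yields the df sequence 6, 6, 12, 15, 21, 27,
18, 21, 24, 27.

**Covariance divisor.** Raw data produce unbiased $(n-1)$ covariances;
these (and moment files, assumed unbiased) are rescaled by $(n-1)/n$
before entering $F_{ml}$, the common normal-theory ML convention.
Population moments produced by the simulator are marked `cov_type =
"ml"` and enter unrescaled.

## 2. Equivalence testing and the T-size

Under ET the null is $H_{e0}: F_{ml0} > \epsilon_0$. With
$\delta_0 = (N - m)\epsilon_0$, $H_{e0}$ is rejected when $T_{ml}$
falls below the left-tail $\alpha$-critical value of
$\chi^2_{df}(\delta_0)$; rejection supports tolerable misspecification
with confidence $1-\alpha$. Instead of fixing $\epsilon_0$,
`tsize()` solves $T_{ml} = c_\alpha(\epsilon_t)$: `invert_ncp()`
finds the noncentrality $\delta_t$ with
$P(\chi^2_{df}(\delta_t) \le T) = \alpha$ and
$\epsilon_t = \delta_t / (N - m)$,
$\mathrm{RMSEA}_t = \sqrt{m\,\epsilon_t/df}$. Rejection at any
prespecified $\epsilon_0$ is equivalent to $\epsilon_t < \epsilon_0$
(a property the test suite checks over a grid).

**Numerics.** The inversion is monotone bisection on $\delta$ over
$[0,\ T + 10\sqrt T + 100]$ (doubled until it brackets), to absolute
tolerance $10^{-10}$, returning 0 when $T$ is at or below the central
$\alpha$-quantile. R's noncentral CDF costs $O(\sqrt{\delta})$, so for
$\delta > 10^6$ (only reachable with absurdly large statistics) a
normal approximation of $\chi^2_{df}(\delta)$ takes over; the switch
is far outside any region where it could affect reported precision.

**Adjusted cutoffs.** Conventional RMSEA anchors (0.01/0.05/0.08/0.10)
are too stringent for $\mathrm{RMSEA}_t$. `adjusted_cutoffs()`
evaluates the published regression formulas
$\exp(b_0 + b_1\log df + b_2 \log^2 df + \dots)$ at the per-group
effective sample size $n = (N-m)/m$. A transcription caveat: the exact
multi-group companion script is not redistributable here; the
coefficients used are the same authors' published single-group
regressions, which reproduce the worked example's df = 6 cutoff row
exactly and its df = 3 and df = 21 rows to within 0.002 — and all 13
of its goodness-of-fit labels exactly. The tests pin this agreement.
A warning is attached outside roughly the fitted range (effective $n$
in [30, 1000], df ≤ 120).

**Labels.** `fit_label()` maps $\mathrm{RMSEA}_t$ to excellent /
close / fair / mediocre / poor by left-closed intervals at the four
cutoffs. One of the source texts lists "0.008" among the conventional
anchors; that is treated as a typo for 0.08, consistent with the
`cut.08` column of the reference output.

## 3. The projection method

Given metric invariance (common $\Lambda$), each group's mean vector
decomposes orthogonally as $\bar x^{(j)} = \hat\mu_\kappa^{(j)} +
\hat\nu^{(j)}$ with $\hat\mu_\kappa^{(j)} = \Lambda\hat\kappa^{(j)}$
the projection onto $\mathrm{col}(\Lambda)$. Cross-group equality of
$\kappa$ (latent means) and of $\nu$ (specific-factor means) are then
separate hypotheses, testable without equal intercepts.

Design choices the methodology leaves open:

* **Projection metric.** The default is the Euclidean orthogonal
  projection $P = \Lambda(\Lambda'\Lambda)^{-1}\Lambda'$; a
  GLS-weighted projection (any positive-definite weight, e.g. the
  inverse pooled implied covariance) is available through the `weight`
  argument. The Euclidean choice is the simplest reproducible reading
  of "orthogonal projection", and the decomposition identity and Wald
  df are metric-independent.
* **Standard errors.** The covariance of the stacked differences
  propagates only the sampling covariance of the group means
  ($S_j/n_j$) through the fixed projection; the sampling variability
  of $\hat\Lambda$ is deliberately ignored in the analytic SEs and is
  instead captured by `bootstrap_mean_tests()`, which refits the
  metric model in every replicate. This simplification is stated,
  testable (the type-I-error suites cover both fixed and estimated
  $\Lambda$), and correctable.
* **Baseline.** Group 1 in input order; Wald statistics are invariant
  to the choice (tested).
* **Divisor for ET on Wald statistics.** The ET formulation for the
  projection Wald statistic states $\delta_0 = N\epsilon_0$, and that
  is the package default (`stat_family = "wald_projection"`). The
  reference implementation's printed output, however, is reproduced
  exactly (3 decimals) only by the $(N-m)$ divisor; both conventions
  are exposed, they differ by well under 0.002 in $\mathrm{RMSEA}_t$
  at the example's scale, and the tests document both facts.
* **Validity index.** $\rho^2_c = 1$ when specific-factor differences
  vanish, $0$ when latent-mean differences vanish, `NA` (undefined)
  when both do. The customary reading — below 0.5 suggests item
  revision, above 0.70 supports interpreting manifest differences as
  latent differences — is advisory and never enforced.

## 4. The synthetic-data generator as a stated world

`sim_design()` defaults emulate the canonical worked setting: two
groups of 78 and 174 observations, three correlated factors
(variances 1, correlations 0.5), two indicators each with marker
loading 1 and secondary loading 0.8, error variances 0.5 (indicator
reliabilities ≈ 0.6–0.75, typical of short literacy scales), zero
intercepts and latent means. Where the reference analysis fixes no
population values (it is a real-data example), these are one-time
choices of a realistic fully standardized CFA; they are not tuned.

Violations are injected one component at a time: `loading_shift`
(breaks metric invariance), `intercept_shift` (breaks scalar
invariance), `specific_mean_shift` (moves group 2's intercepts along a
unit vector orthogonal to $\mathrm{col}(\Lambda)$, so the population
$\kappa$ difference stays 0 while $\nu$ differs), `latent_mean_shift`
(the converse). `calibrate_violation()` root-finds the shift whose
*population* misfit — the minimized $F_{ml}$ of the relevant
constrained model evaluated at exact population moments — equals a
requested target, tying violation magnitudes to the $\epsilon$ scale
of Section 2.

The generator draws exact multivariate normals and is fully seeded.
It does **not** emulate non-normal indicators, ordinal items, missing
data, or cluster structure; a green test here therefore establishes
the normal-theory calculus, not robustness to those features (which
the underlying theory itself defers).

## 5. Optimization and numerical choices

* Free parameters are shared across groups exactly as the constraint
  set dictates (no post-hoc averaging). Per-group free intercepts with
  latent means fixed at 0 are profiled out analytically
  ($\gamma_j = \bar x_j$), shrinking the search space for half the
  models.
* The minimizer is `nlminb` on the direct parameter scale with a
  finite guard value where $\Sigma$ is not positive definite, a polish
  rerun from the solution, and a numerical-gradient convergence check
  (sup-norm below $5\times10^{-4}$ on the $F_{ml}$ scale, relaxed
  proportionally for large misfit). An unconstrained
  reparameterization (log variances, Cholesky factors) was considered
  and rejected: parameter sharing handles the equality constraints
  either way, and the direct scale keeps Heywood cases (negative error
  variances) visible, which the error contract requires — they are
  reported with a warning, not hidden by a transform.
* On a failed check, up to 5 deterministic seeded restarts alternate
  between jittered warm starts and jittered data-driven defaults. A
  warm start mapped from a less-constrained parent (the sequence warm
  starts each child from its parent's estimates) can land where
  $\Sigma$ is not PD — e.g. after a Heywood parent fit — in which case
  the data-driven start is used instead of optimizing on the guard
  plateau.
* Convergence failures are flagged on the result (`converged`), never
  silently dropped; the sequence propagates per-row failures without
  aborting.
* Moment files are validated with a relative symmetry tolerance of
  $10^{-8}$ (symmetrized below it, rejected above); negative
  difference statistics are reported with a warning rather than
  truncated.

## 6. What the test suite establishes

* The equivalence calculus reproduces all published T-size rows of the
  worked example from their printed statistics, and the df accounting
  reproduces the printed df columns exactly. The fitted chi-squares of
  that example are *inputs* (its raw moments live in an external
  table), so the ML machinery is validated differently: closed-form
  and brute-force oracles, population-moment identities ($F_{ml} \le
  10^{-8}$ with parameter recovery), nesting monotonicity, and
  independently coded constrained-fit comparisons.
* The 2000-replication type-I-error check of the Wald tests supplies
  the population $\Lambda$ (isolating the quadratic-form calculus and
  keeping the suite inside its time budget); a 60-replication check
  with estimated $\Lambda$ and the bootstrap calibration cover the
  plug-in effect. Similarly, the 2000-replication null calibration of
  $T_{ml}$ uses the closed-form covariance-equality statistic, with a
  30-replication version exercising the iterative fits.

## 7. Known limitations

Only measurement models (`=~` lines): no structural regressions,
residual covariances, ordinal/categorical indicators, or missing-data
handling. No robust (rescaled) statistics. No automated search for
partially invariant subsets — when metric invariance fails, the user
chooses the invariant subset and reapplies the projection. The
adjusted-cutoff coefficients carry the transcription caveat of
Section 2.
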