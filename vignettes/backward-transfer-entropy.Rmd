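---
title: "Backward transfer entropy: models, bounds and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backward transfer entropy: models, bounds and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bteflow)
```

This vignette is the package's account of what it computes and why the
numerical design looks the way it does.  Everything stated here is
checked by the test suite on exactly enumerable models; nothing is an
empirical claim beyond what those computations show.

## The setting

We consider two interacting discrete-time processes $X$ and $Y$ over
steps $k = 1,\dots,N$ on finite alphabets.  The canonical generative
class in the package is the *delayed bipartite Markov model*
(`bipartite_model()`): within each step the target updates first,
$y_{k+1} \sim q(\cdot \mid y_k, x_k)$ (a measurement of the source),
and the source then updates,
$x_{k+1} \sim w(\cdot \mid x_k, y_{c(k)})$ with the delayed
conditioning index $c(k) = \max(k - n, 1)$ (feedback from a possibly
stale record; $n = 0$ is Markovian interacting dynamics).  The boundary
rule conditions on $y_1$ whenever the delay reaches past the start.
Because the source update never reads the fresh target state, the
one-step joint kernel factorizes; the variant `x_cond = "fresh"`
(used by the instantaneous sensor model) instead redraws
$x_{k+1}$ from the *current* $y_{k+1}$.

All information quantities are in nats.  With the Boltzmann constant
set to 1, entropies, transfer entropies and entropy production are then
directly commensurable; `in_bits()` converts for display only.

## Forward and backward information flow

Transfer entropy with history $l$ at step $k$ is the conditional mutual
information
$I_{tr}(k,l) = I(X_{k-l+1:k};\, Y_{k+1} \mid Y_{k-l+1:k})$.
The backward transfer entropy is *defined* as the transfer entropy of
the time-reversed pair of series, which in forward indices reads
$I_{BT}(m,l) = I(X_{m+1:m+l};\, Y_m \mid Y_{m+1:m+l})$.
The package implements it literally as reversal followed by TE
(`backward_transfer_entropy()` calls `reverse_paths()` and
`transfer_entropy()`), because that is the only reading under which
every claimed identity — the involution property, equality with the
directly-evaluated conditional mutual information, and the directed
information relations — holds mechanically for every $l$.

The one-step BTE vanishes exactly when the Markov chain
$Y_m \to Y_{m+1} \to X_{m+1}$ holds, i.e. when the source is an
instantaneous noisy read-out of the target: a hidden Markov model.
BTE is therefore a distance-from-hidden-Markov measure, which motivates
both the surrogate test below and the sensory capacity
$C = 1 - I_{BT}/I_{tr}$ evaluated in the stationary state.  The
orientation of that ratio was a genuinely open choice (the
learning-rate-to-TE ratio could be written either way up); we fixed
$C = 1 - I_{BT}/I_{tr}$ because it is the unique orientation with
$C \le 1$ always and $C = 1$ exactly at $I_{BT} = 0$, and in the
stationary state it coincides with the learning rate divided by the
transfer entropy.  `sensory_capacity()` refuses models whose stationary
TE vanishes (the ratio is then undefined) and models without a unique
stationary law.

Directed information sums transfer entropies with *maximal* histories
plus the initial mutual information; its backward counterpart is the
directed information of the reversed paths.  Using full histories in
the sums is what makes the thermodynamic and gambling identities below
exact rather than approximate.

## Thermodynamic bounds and the fluctuation theorem

For a lagged-feedback model, the pathwise bath entropy of the source is
defined through local detailed balance,
$\Delta S_{bath} = \sum_k \ln \frac{w(x_{k+1}\mid x_k, y_{c(k)})}
{w(x_k \mid x_{k+1}, y_{c(k)})}$,
with the backward transition probability given by the argument-swapped
forward kernel — valid because no variable in this class is
momentum-like (odd under time reversal).  The system entropy change is
$\Delta s_x = \ln p_1(x_1) - \ln p_N(x_N)$.

The generalized entropy production is constructed, deliberately, as
$\sigma = \ln\!\big[p(\text{path}) / P_B(\text{path})\big]$
for an *explicitly normalized* reference path measure $P_B$.  This
single design decision buys three exact identities at once: the
integrated fluctuation theorem $\langle e^{-\sigma}\rangle = 1$
(the sum over paths of $P_B$), the representation
$\langle\sigma\rangle = D_{KL}(p \,\|\, P_B) \ge 0$ (computed in the
package by literally building both measures and calling
`kl_divergence()`), and the decomposition of $\sigma$ into
$\Delta S_{x+bath}$ plus stochastic information integrands.

Two reference measures are used:

* the **weak** measure draws the whole target path from its marginal,
  the final source state from its marginal, and runs the source chain
  backwards with the swapped kernel at the forward delay conditioning.
  Its $\sigma_{weak}$ averages to
  $\langle\Delta S_{x+bath}\rangle + DI$, giving the weak bound
  $\langle\Delta S_{x+bath}\rangle \ge -DI$ for every delay $n$;
* the **tight** measure additionally refines the target block.  For
  $n = 0$ the target path can be generated backwards through its
  reversed-time conditionals, and the subtracted information is the
  full backward-transfer-entropy sum plus the final-time mutual
  information: the bound becomes
  $\langle\Delta S_{x+bath}\rangle \ge
  \sum I_{BT} + I(X_N;Y_N) - \sum I_{tr} - I(X_1;Y_1)$.
  For $n \ge 1$ a backward generative order cannot condition the
  swapped kernel on a target state that has not yet been generated, so
  the target block is coarsened to $p(y_{1:N})\,p(x_N\mid y_{1:N})$ and
  the subtraction becomes $I(X_N; Y_{1:N})$.  The difference from the
  full BTE sum is reported as the delay correction
  $\langle\xi\rangle = \sum I_{BT} + I(X_N;Y_N) - I(X_N;Y_{1:N}) \ge 0$
  (a sum of conditional mutual informations), and it is identically
  zero in the construction at $n = 0$.

We note a design alternative that was implemented, tested and
rejected: reversing the *delay itself* in the backward kernel
(conditioning on $y_{\min(k+n,N)}$) also yields a normalized reference
measure and an exact fluctuation theorem, but the resulting "tight"
bound is not tighter than the DI bound on random delayed models.  The
coarsened-target construction above is the one under which
$0 \le \text{tight gap} \le \text{weak gap}$ holds by construction for
all delays, which the sweep tests confirm.

For $n = 0$ the tight bound is additive: the per-step quantity
$B_k - T_k + I(X_{k+1};Y_{k+1}) - I(X_k;Y_k)$, with single-step
$T_k = I(X_k;Y_{k+1}\mid Y_k)$ and $B_k = I(X_{k+1};Y_k\mid Y_{k+1})$,
telescopes exactly to the full-history total
(`stepwise_tight_bound()`); the cancellation behind this is an identity
of the Markov property and is asserted to $10^{-10}$.

The exact fluctuation-theorem and KL identities hold on the support of
the forward measure; `entropy_production()` therefore checks that the
reference measure's mass on that support is 1 and refuses otherwise.
In practice this means kernels should be strictly positive — the random
model generator guarantees it, and paths of probability exactly zero
are excluded throughout.

## Gambling with side information

In the horse-race setting the winners are the target process and the
side information the source.  The gambler's accessible set before race
$k$ is $\{s_1,\dots,s_{k-1}\}$ plus past winners (and $s_1$ for the
first race — this is what produces the initial mutual-information term
in the bound).  Kelly bets are the accessible-history conditionals;
with causal fair odds $1/o_k = p(y_k \mid y_{1:k-1})$ the expected
log-growth satisfies $\langle G\rangle \le DI$ with equality exactly at
Kelly, and the gap is again a KL divergence.  The cheating bookmaker
sets anti-causal fair odds from the future,
$1/o_k = p(y_k \mid x_{k+1:N}, y_{k+1:N})$ for $k < N$ and
$p(y_N \mid x_N)$ at the horizon; the bound becomes
$\langle G\rangle \le \sum I_{tr} - \sum I_{BT} + I(X_1;Y_1) -
I(X_N;Y_N)$, term-by-term the mirror of the $n = 0$ tight
thermodynamic bound (the tests assert the two right-hand sides agree on
a shared process).  The anti-causal conditioning set is configurable in
principle, but the full future $(X_{k+1:N}, Y_{k+1:N})$ is the default
because it is the set under which the growth identity for Kelly bets is
exact.  Wealth is carried in log space; probability-zero contexts carry
no bets or odds and are excluded from the sums.

## Gaussian processes and (anti-)causality

For the stationary bivariate VAR(1)
$x_{k+1} = a x_k + \xi_k$, $y_{k+1} = b y_k + c x_k + \eta_k$ the
stationary covariance of a $W$-step window comes from the discrete
Lyapunov equation (residual checked to $10^{-10}$), and every
information measure is a log-determinant ratio
(`gaussian_cmi()`).  Granger causality is the log ratio of restricted
to full residual variances when predicting $y_{k+1}$; the
anti-causality measure predicts the *past* $y_m$ from the future
$y_{m+1:m+l}$ (restricted) and additionally $x_{m+1:m+l}$ (full) — the
nested difference isolates exactly the BTE conditioning pattern, which
is why `antiGC` $= 2\,I_{BT}$ holds to $10^{-10}$ alongside
`GC` $= 2\,I_{tr}$.

Two numerical conventions matter for exactness.  Residual variances use
the maximum-likelihood divisor $n$, not $n - p$: only then do the
regression measures coincide with the entropy identities.  Intercepts
are always included and data are never pre-centred.  On data, the OLS
route and the Gaussian plug-in route (log-determinants of the sample
covariance of the same embedded records) satisfy the factor-2 identity
exactly by construction; convergence to the model truth is a separate
statement, asserted at $|{\;\widehat{GC} - GC\;}| \le 0.01$ nats for
$10^5$ observations.  Rank-deficient designs fall back to the
pseudo-inverse with a warning.

## Estimators and the hidden-Markov surrogate test

Discrete-series estimation is plug-in only: the exact information
functional applied to the empirical frequency table of the
delay-embedded series, with no bias correction.  This keeps the
estimator exactly the population functional of the empirical measure —
bias corrections (Miller–Madow and relatives) would break the identity
structure the package trades on, and for the binary fixtures the
plug-in bias at $10^5$ observations is far below the 0.02-nat tolerance
the tests use.

`hmm_detection()` tests the null hypothesis that the one-step
conditional independence $X_{m+1} \perp Y_m \mid Y_{m+1}$ holds.
Because the null is a *conditional* independence, naive shuffling is
wrong; the surrogate scheme resamples, for every record, the source
state from the empirical conditional $\hat p(x \mid y_{m+1})$, which
enforces the null while preserving the instantaneous coupling and the
target's own dynamics.  The decision compares the observed plug-in BTE
with the empirical $1-\alpha$ null quantile (type-7), $\alpha = 0.05$
by default, with at least 19 surrogates required.  The statistic is
fixed at $l = 1$ because that is the exact characterization of the
hidden-Markov property; larger-$l$ BTE estimates remain available
through `bte_plugin()`.

## The synthetic models: what they emulate and what they do not

All fixtures are generated in code:

* `make_hmm_sensor(p_meas = 0.2, p_obs = 0.1)` — an instantaneous
  binary sensor: the signal copies the previous sensor state with error
  0.2 and the sensor redraws from the current signal with error 0.1.
  By construction BTE $\equiv 0$ and the stationary capacity is 1.
* `make_coupled_binary()` — a generic Markovian pair with both flows
  positive; the default kernels were fixed once (from a seeded scan of
  stochastic kernels) so that the stationary TE (≈ 0.19 nats) exceeds
  the stationary BTE (≈ 0.14 nats), keeping the capacity inside
  $(0,1)$ as a generic sensor should be.
* `make_demon()` — a measurement-feedback demon.  Getting
  $\langle\Delta S_{x+bath}\rangle < 0$ requires the system's actual
  alignment with the measurement record to exceed the feedback
  kernel's own equilibrium bias, so the defaults use an accurate
  measurement (error 0.05), a weakly biased detailed-balance kernel
  ($\delta = 0.35$, attempt rate 0.5) and a correlated initial joint
  (misalignment 0.1); the negativity is re-verified by enumeration at
  construction.
* `var1_model(0.5, 0.3, 0.4, 1, 1)` — the Gaussian fixture; stability
  is enforced at construction.
* `make_race()` — a two-horse race whose winners are influenced by an
  autonomous side-information channel, giving strictly positive
  directed information.

These models emulate the *structure* real bipartite data can have —
delays, instantaneous read-outs, feedback — at binary (optionally
ternary) alphabets where exact enumeration is the oracle.  They do not
emulate long-memory sources, nonstationarity, continuous state spaces
(beyond the linear-Gaussian family), or measurement with correlated
noise; a passing suite therefore certifies the estimators and
identities, not robustness of the surrogate test to those violations.

## Problem sizes and numerical choices

Exact enumeration is used up to $10^7$ paths (beyond that the API
directs users to seeded Monte Carlo).  The verification sweeps use 50
random strictly-positive binary models with delays $n \in \{0,1,2\}$
and horizons $N \in \{3,4,5\}$; estimator checks use single stationary
series of $10^5$ steps; the Gaussian OLS checks use $10^5$
observations; the race bounds use 20 random games.  Stationary
distributions are the leading eigenvector of the composite one-step
kernel, validated to a $10^{-12}$ fixed-point residual after an
irreducibility check on the transition graph.  Probabilities below
$10^{-15}$ are treated as exact zeros in support checks; $0 \ln 0 = 0$
throughout; a KL divergence with failed absolute continuity is returned
as an explicit `Inf`, never an exception.  Identity-type assertions are
made in absolute nats ($10^{-10}$ or $10^{-12}$), statistical ones at
tolerances dominated by sampling error (0.01–0.02 nats).

## Known limitations

Only pairwise (two-subsystem) flow is implemented — no multivariate
conditioning, no spectral Granger measures, no continuous-time limits.
The plug-in estimators are consistent but biased at small samples, and
the surrogate test's power depends on the alphabet-to-sample ratio (the
report carries a warning field when that ratio is unfavourable).  The
delayed-dynamics tight bound is one principled reconstruction among
the family of normalized-reference-measure bounds; it is exact and
ordered by construction, but sharper delayed bounds may exist.
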