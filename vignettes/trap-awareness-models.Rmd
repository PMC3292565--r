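---
title: "Modelling trap dependence as a change of state"
author: "trapaware"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trap dependence as a change of state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapaware)
```

## The model and its assumptions

Open-population capture–recapture data consist of encounter histories:
one row per marked animal, one column per capture occasion, codes 0/1 (or
0/1/2 when two states of interest are distinguished). The
Cormack–Jolly–Seber (CJS) model conditions on each animal's first capture
and estimates survival probability φ per interval and capture probability
p per occasion, assuming successive captures are independent given
survival. In a large fraction of field studies they are not: capture at
*t* changes the probability of capture at *t+1*.

`trapaware` models the *immediate* trap effect on capture (ITEC): the
response lasts exactly one occasion, and an animal missed once reverts to
its naive state. The key idea is to treat the response as a Markovian
change of state. Assessed at the end of each capture session, an animal is
*trap aware* (A) if it was just captured — its necessary state at initial
release — and *trap unaware* (U) otherwise; together with the absorbing
dead state these are the operational states of a hidden Markov (multievent)
model. The one-interval transition matrix factorizes into a survival
process S acting between sessions and a trap-awareness process P that
resolves capture at the next session:

$$
\Pi = S\,P,\qquad
\Pi = \begin{pmatrix}
\varphi p' & \varphi(1-p') & 1-\varphi\\
\varphi p  & \varphi(1-p)  & 1-\varphi\\
0 & 0 & 1
\end{pmatrix}
$$

over states (A, U, dead), with p′ the capture probability of aware
animals (`pA` in the package) and p that of unaware animals. The event
matrix is degenerate — A emits "encountered", U and dead emit "not
encountered" — so capture probabilities sit among the *transitions*, not
the emissions: capture genuinely effects (or reveals) a change of state.
Defining awareness at the session's *end* rather than its start is what
makes losses on capture (censored animals) trivial to handle: a removed
animal simply contributes no terms after its removal occasion.

The multistate version crosses awareness with two states of interest
(sites, breeding states): operational states A1, U1, A2, U2, dead, and a
three-step factorization Π = S·T·P where T moves animals between states of
interest (preserving awareness) by the end of the interval, with
probabilities ψ12, ψ21. For example the entry A1 → U1 is
φ¹ψ¹¹(1−p′¹): survive, stay, miss capture. At release an animal is aware,
in state 1 with probability π1; captured animals have their state
recognized without error (A1 emits code 1, A2 code 2).

Why states and not split histories? The classical fix cuts every history
after each capture and models the first post-release occasion with its own
capture class — correct, but awkward (one animal becomes many pseudo-
individuals, and interactions with age structure are error-prone). The
state formulation needs no data surgery and the two are algebraically
equivalent: conditioning on a capture collapses the forward distribution
to the aware state, so the state likelihood factorizes exactly into the
fragment terms of the split-history CJS. The package implements both
(`itec(..., method = "state")` and `method = "split"`) and the test suite
verifies the maximized log-likelihoods agree to 1e-6 and the MLEs to 1e-4.

## Likelihood and conditioning

The likelihood of a history is computed by the forward algorithm,
conditioning on first release in the aware state (CJS-style: the first
capture itself is not modelled). For two-state data the recursion starts
in the aware state of the *observed* release state. Because the release
state is observed without error, the initial-state probability π1 factors
out of the conditional likelihood; it is therefore not an estimated
parameter by default, but `history_loglik()` accepts a `pi1` value and
then includes the π1 / (1−π1) term for users who want the unconditional
formulation.

Transience — newly marked animals that permanently emigrate, depressing
apparent first-interval survival — is the standard two-age-class device:
survival over the first interval after marking is φ1, φ2 afterwards
(`effects_phi = "transience"`). In the split-history formulation only an
animal's *first* fragment carries φ1, which is required for the
equivalence to hold in the presence of transients.

## Parameters, effects and defaults

| parameter | meaning | link | where |
|---|---|---|---|
| `phi` (or `phi1`, `phi2`) | survival per interval | logit | all models |
| `p` | capture of trap-unaware animals, occasions 2..K | logit | all models |
| `pA` | capture of trap-aware animals | logit | `effects_p` contains `"trap"` |
| `m` | additive trap effect, `logit pA_t = logit p_t + m` | identity | `"additive"` (requires `"time"` and `"trap"`) |
| `psi12`, `psi21` | transitions between states of interest | logit | two-state |
| `pi1` | initial state-1 probability | — | two-state, conditioned out by default |

`itec_model()` validates the combinations (`"additive"` without `"time"`
is refused; the two-state surface is constant-parameter only — the S·T·P
construction generalizes, but only the two-state case is tested).
Dropping `"trap"` from `effects_p` gives the naive CJS, and then the state
formulation and the independent alive/dead CJS recursion used by
`method = "naive"` agree to 1e-6 — a deliberate dual-route check.

## Numerical choices

* **Link and optimizer.** All probabilities are estimated on the logit
  scale (m on its own unbounded scale) by BFGS with a central-difference
  gradient (step `1e-5 * (1 + |θ|)`), relative objective tolerance 1e-12,
  at most 500 iterations, default start 0 on the link scale; optional
  random restarts are drawn N(0, 1.5²) behind one explicit seed.
  Non-convergence is reported in the `converged` flag, never silently.
* **Uncertainty.** Covariance is the inverse observed Hessian
  (gradient-difference `optimHess`); 95% intervals are Wald on the link
  scale, back-transformed, so they always lie in (0, 1) and bracket the
  estimate.
* **Identifiability.** Eigenvalues of the correlation-scaled Hessian below
  1e-6 flag confounded directions; the parameters loading on them
  (|eigenvector| > 0.3) are reported in `rank_deficient` with their CIs
  suppressed, never dropped. The fully time-dependent CJS reproduces the
  textbook confounding of φ_{K−1} with p_K this way. Estimates beyond
  |logit| > 12 are flagged `boundary` and their CIs suppressed rather than
  fabricated.
* **Underflow.** Forward masses are floored at 1e-300 inside the
  optimizer only; user-facing likelihoods may legitimately be `-Inf` at
  boundary parameter values.
* **Not-operated sessions** are not a data code; fix the corresponding
  `p_t` by supplying time-varying parameters instead.

## Test 2.CT: construction and conventions

The diagnostic contrasts, at each occasion i in 2..K−2, animals
encountered at i against animals not encountered at i but known alive
(encountered before and after i), restricted to those encountered again
after i, split by whether the next encounter is immediate (i+1) or
delayed. Under independence both rows share one immediate-recapture
proportion. The per-table component is the uncorrected Pearson chi-square
— chosen because the overall statistic sums components, and summed
Yates-corrected components are conservative, miscalibrating the nominal
level (the correction remains available via `correct = TRUE`). When any
expected cell is below `exact_threshold = 2`, the component is the
chi-square(1) quantile of the Fisher exact p-value. The overall statistic
is the sum over informative tables (df = their number); the directional
statistic is

$$ z = \sum_i \mathrm{sign}_i \sqrt{\chi^2_i} \, / \sqrt{\mathrm{df}}, $$

signed positive when captured-at-i animals are recaptured immediately
more often (trap-happiness). Published software descriptions differ on
whether pooling happens before or after signing; this construction is
declared as the package's convention, and the tables are printed so it
can be audited. The suite checks calibration (type-I error at 5% within
exact binomial 99% bounds over 400 null replicates, component mean ≈ 1),
power (> 90% at p′ = 0.8, p = 0.3, n = 1000, K = 8) and the sign
convention in both directions.

## What the simulator emulates — and what it does not

`simulate_itec()` draws histories from the exact generative process:
cohorts released (first captured) at occasions 1..K−1, aware at release,
evolving by the S(·T)·P factors; transients as a mixture at release
(apparent first-interval survival (1−tf)·φ); removals as per-capture
censoring. The random stream is consumed in a fixed documented order
(cohort, individual, occasion; survival, transition, capture, removal),
so a seed yields byte-identical data. `history_pattern_probs()` provides
the matching exact enumeration (K ≤ 5) by brute-force path summation,
deliberately independent of the forward recursion, and the suite checks
simulator, enumerator and forward algorithm against one another.

The simulator deliberately reproduces the model's own assumptions. It
does *not* generate lasting or waning trap effects, individual
heterogeneity in catchability, density dependence, individual covariates
or continuous-time entry. Passing tests therefore demonstrate correctness
of the implementation under an immediate one-occasion response, not that
real data satisfy that assumption — for sighting dependence that persists
across occasions (territory overlap, fixed heterogeneity) mixture or
temporary-emigration models are more appropriate, and the state approach
would need semi-Markov holding times in the aware state (an extension
hook, not implemented).

## Study designs used by the test suite

Problem sizes were chosen to make Monte-Carlo error small relative to the
tolerances tested: formulation equivalence on 800 animals over 8 occasions
(staggered cohorts, transients φ1 = 0.6 / φ2 = 0.85, p = 0.4, p′ = 0.7);
parameter recovery and the naive-CJS bias direction on 200 replicates of
one cohort of 500 animals followed over 8 occasions (φ = 0.8, p = 0.4,
p′ = 0.7) — a single marked cohort is used there because Wald intervals
are skew-sensitive in small late-release cohorts; Test 2.CT calibration on
400 null and 200 trap-happy replicates of 1000 animals. The oracle checks
run at K = 4, 5 where full path enumeration is exact and cheap.

## Known limitations

* The two-state surface is constant-parameter; time-varying multistate
  structures are not exposed.
* Wald intervals only; no profile likelihood. Boundary and confounded
  parameters get flags instead of intervals.
* Under the additive time + trap structure the terminal parameters can be
  weakly identified; the package reports rank deficiency rather than
  imposing an identifying constraint.
* Goodness of fit is limited to Test 2.CT; the multistate omnibus test
  and the remaining CJS component tests are out of scope.
* E-SURGE-style "headed" project files are not parsed; MARK `.inp` and
  CSV (wide or long) are the supported formats, and `write_inp()` on a
  `split_histories()` set reproduces the traditional censored coding for
  cross-validation in external software.
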