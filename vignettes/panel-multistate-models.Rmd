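---
title: "Multi-state models for panel data with unobservable features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state models for panel data with unobservable features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelmsm)
```

# Scope

`panelmsm` fits continuous-time Markov multi-state models to *panel data*:
subjects observed only at intermittent visits, with the state path between
visits interval-censored.  Four model classes share one declarative
specification (`pm_spec`) and one likelihood engine:

1. **Semi-competing risks with an unobservable state** — a five-state model
   (healthy H, observed non-fatal event NF, loss to follow-up LTF, an
   unobservable post-LTF non-fatal event NF(LTF), and death F) in which
   mortality is always observed but the non-fatal process is silenced after
   loss to follow-up.  Identifiability requires
   $\lambda_3 \equiv \lambda_7$ and the ratio constraint
   $\lambda_1/\lambda_2 = k\,\lambda_5/\lambda_6$, with $k>0$ a fixed,
   non-estimable sensitivity parameter.
2. **Expanded state-space joint model** — an ordinal outcome $Y$ ($m$
   levels, adjacent-state reversible) observed jointly with a rapidly
   fluctuating ordinal covariate $W$ ($n$ levels) on the $m \times n$
   lattice, with constraints that keep $W$ a *predictable* covariate:
   regression coefficients on $Y$-moves shared across $W$ levels, and
   $W$-move rates shared across $Y$ states.  The carried-forward
   "misspecified" $m$-state model is provided as the comparator.
3. **Hidden-state remission model** — active disease S1, early remission
   S2, established remission S3 with transitions S1→S2→S3→S1, fitted to
   observed codes O1/O2/O3 derived from active-joint counts through a
   misclassification (emission) matrix in which only S1 can be
   misclassified: $\Pr(O_2\mid S_1)=\mathrm{logit}^{-1}(\gamma^T z)$.
4. **Clustered paired-organ damage model** — a four-state progressive
   process per joint location (no damage, right damaged, left damaged,
   both), baselines shared across the 14 hand locations, symmetry offsets
   $\lambda_{024}=\lambda_{013}e^{\gamma_{24}}$,
   $\lambda_{034}=\lambda_{012}e^{\gamma_{34}}$, and a unit-mean gamma
   frailty with variance $\theta$ shared by all of a subject's locations.

# The likelihood engine

## Intensities

Every transition has a proportional intensity
$\lambda_{jk}(t)=\lambda_{0jk}(t)\exp(\beta_{jk}^T x(t))$ with a baseline
from one of three families: constant, piecewise constant (left-closed,
right-open intervals, hazard right-continuous at cutpoints), or Weibull.
The Weibull is parameterized with hazard $a\,b\,t^{b-1}$ and cumulative
hazard $a\,t^b$; the source analyses cite a Weibull baseline without
printing a parameterization, and this one was chosen for its closed-form
cumulative hazard (any monotone reparameterization is equivalent).

Equality constraints are shared parameter labels; two derived-baseline
rules cover the constraint systems above: a *ratio product*
$\lambda_5(t)=\lambda_1(t)\lambda_6(t)/(k\lambda_2(t))$ (closed under the
power-law hazards, with the regression coefficients combined as
$\beta_1+\beta_6-\beta_2$), and an *exp offset*
$\lambda_{0t}=\lambda_{0s}e^{\gamma}$.

## Panel likelihood

Covariates are carried forward from the last visit, and the generator
$Q(t)$ is treated as constant on the sub-intervals obtained by splitting
each inter-visit gap at baseline cutpoints.  Transition matrices are
ordered products of matrix exponentials (dense scaling-and-squaring Padé,
via Armadillo), computed once per distinct (generator, length) pair per
evaluation.  A Weibull baseline varies continuously, so gaps are further
subdivided on an *absolute* grid of step `meta$time_step` (default 0.25;
0.125 for the five-state model) and the generator is evaluated at the
midpoint of the containing grid cell.  Anchoring the grid and the
evaluation point to the cell — rather than to the segment — makes the
approximation *consistent*: splitting an interval at any interior point, or
chaining Chapman–Kolmogorov products, reproduces the unsplit result to
machine precision, while the discretization error itself is $O(h^2)$.

Observation records may be a single state, a censoring set (`"1,2"`, or
`"*"` for fully unknown — the likelihood sums the transition probabilities
over the set), or an *exact transition* (`exact = 1`), used for event times
observed in continuous time such as deaths.  Exact records follow the
"exact times" convention of the field's standard software: the state is
known to be constant up to the recorded transition, so the gap contributes
the sojourn survival $\exp(q_{jj}\,\Delta t)$ times the transition
intensity at the event time.  (For progressive graphs this coincides with
the interval-censored matrix entry; in reversible graphs only this reading
makes the likelihood of a fully observed path equal the product of sojourn
densities and jump intensities, which the test suite verifies against an
analytic oracle.)  Setting `meta$exact_times = TRUE` applies the
convention to every gap.

Hidden-state models weight the forward vector at each visit by the
emission probabilities of the observed code; the recursion is scaled at
each visit, so underflow cannot occur.  A forward-algorithm evaluation
equals a brute-force enumeration over all hidden-state sequences to
1e-10 (tested on 3 states x 4 visits).

## Left truncation

The default likelihood conditions on the state at the first observation.
The remission model instead anchors subjects in S1 at the diagnosis time
origin: the hidden-state distribution at the (possibly much later) first
visit is the occupancy row $P(0,t_{\text{first}})[S_1,\cdot]$, weighted by
the first visit's emission and renormalized — i.e. the likelihood
conditions on the first observation but propagates the delayed-entry
occupancy.  This is clinically motivated (active disease at diagnosis) and
is a switch (`condition_entry`) in `build_remission_model()`.

## The five-state semi-competing likelihood

With exact event times the pre-LTF likelihood is closed-form (Weibull
cumulative hazards and hazards).  After an exact LTF at $l$ the subject's
state is marginalized over $\{$LTF, NF(LTF)$\}$.  Because the post-LTF
sub-chain is progressive, the marginal probabilities are one-dimensional
integrals over the unobserved non-fatal event time; they are computed by
25-node Gauss–Legendre quadrature rather than the Runge–Kutta integration
one would need for a general graph.  An RK4 solver for the full
Kolmogorov forward system (`whitehall_occupancy`) is retained as the
independent cross-check and for occupancy summaries; the test suite also
checks the quadrature against a $\Delta t = 10^{-4}$ discrete-time chain.
The cumulative incidence of a first coronary event uses the identity that
H and LTF are exactly the event-free states: $CIF(t)=1-p_H(t)-p_{LTF}(t)$.

## Gamma-frailty marginalization

The marginal cluster likelihood
$\int_0^\infty L(\text{cluster}\mid u)\,dG(u;\theta)$, with $G$ the
unit-mean gamma of variance $\theta$, is integrated by generalized
Gauss–Laguerre quadrature (order 30 by default) with log-sum-exp
stabilization.  The rule is *exponentially tilted*: the dominant decay
rate $b$ of the conditional log-likelihood (its slope between $u=1$ and
$u=2$) is absorbed into the quadrature measure
$\mathrm{Gamma}(1/\theta,\,1/\theta+b)$.  Pure-survival clusters, whose
marginal is the Laplace transform $(1+\theta\Lambda)^{-1/\theta}$, are
then integrated exactly at any order, and general clusters to well below
1e-6 at order 30 (doubling the order is also verified to move cluster
log-likelihoods by less than 1e-6).  $\theta=0$ degenerates to the
conditional likelihood at $u=1$.

Because the four-state damage chain is progressive and acyclic, its
within-gap transition probabilities have closed forms (differences of
exponentials, with a series fallback when exit rates nearly coincide);
`fit_msm()` uses this fully vectorized route, which is tested for
equality (1e-8) against the generic matrix-exponential route.

# Estimation

`fit_msm()` maximizes the appropriate likelihood by BFGS on the
unconstrained working scale (log for positive parameters, identity for
coefficients and offsets), with numerical gradients, starting from crude
per-transition occurrence/exposure rates (coefficients 0, Weibull shapes
1, $\theta$ at 0.1).  Transition matrices whose entries overflow the
$[0,1]$ range (possible when a line search tries an absurd rate) invalidate
the evaluation instead of returning spurious positive "log-likelihoods".
Uncertainty comes from the observed information (numerical Hessian at the
optimum); a singular information matrix falls back to a pseudoinverse with
a warning, which legitimately happens when a piecewise interval has
essentially no exposure.  `lr_test()` and `wald_summary()` provide the
comparison machinery; estimates at the zero boundary are flagged.

# Synthetic data: the stated world

No cohort behind the four applications is publicly deposited, so every
likelihood is exercised on seeded synthetic data (`scenario_library()`),
chosen once to emulate the observation schemes:

* **Remission** (`sim_remission`): 400 subjects, 12 roughly annual visits
  (gamma-jittered gaps, mean 1 year), delayed entry uniform on 0–3 years
  after diagnosis.  True rates $q_{12}=0.15$, $q_{23}=2.0$,
  $q_{31}=0.25$ per year: remission onset is rare, the early stage is
  short-lived by design (it exists to give remission a duration), and
  relapse from established remission is occasional.  Emission
  $\gamma_0=-1$, $\gamma_Z=2$: a sampling zero is likelier at the first
  zero visit (0.73) than the second (0.27), mirroring the reported pattern
  of misclassification probabilities falling from the first to the second
  zero visit.  Two generators are provided: `mechanism = "counts"` draws
  active-joint counts mechanistically (zero iff in remission, sampling
  zeros in S1 with the logistic probability, a third consecutive zero
  structurally impossible under S1) and is what the recoding and the Model
  A/B/C comparisons consume; `mechanism = "model"` draws codes from the
  Model A emission law itself and is the basis of parameter-recovery
  checks, because fitting Model A to mechanistic counts is intrinsically
  (and per the model's pragmatic design) slightly misspecified — the
  emission matrix says $\Pr(O_2\mid S_3)=0$ and $\Pr(O_3\mid S_2)=0$,
  while count recoding can produce both.
* **Five-state cohort** (`sim_whitehall`): 2000 subjects over a 15-year
  administrative window; Weibull rates giving roughly 8% observed
  non-fatal events, 4% deaths and 30% loss to follow-up — event
  frequencies of the right order for a middle-aged occupational cohort.
  After a simulated LTF only the death time (if any) is kept.
* **Joint (Y, W) panel** (`sim_expanded`): 300 subjects, 10 annual
  protocol visits (a fixed shared schedule, as in a clinic protocol);
  $W$ switches fast (rates around 1/year) with a strong true $W$ effect on
  the upward $Y$ moves (log rate ratios up to $\log 4$), the regime in
  which carrying $W$ forward visibly attenuates its estimated effect.
* **Damage** (`sim_damage`): 300 subjects x 14 locations, 11 annual
  visits, one gamma draw per subject ($\theta=0.5$), baselines 0.02/year
  and symmetry offsets $\gamma_{24}=\gamma_{34}=1$.  Joint-level activity
  indicators evolve as a persistent two-state visit-level process
  (zero-inflated: most joints inactive most of the time), effusion given
  activity with probability 0.4, and "ever active" as the running maximum
  — none of which pretends to model real activity dynamics; it only
  supplies covariates with realistic persistence.

What a green test establishes is therefore *methodological*: the
estimators recover known parameters from data generated by the stated
models at realistic sizes, and the qualitative findings (attenuation under
carried-forward covariates; the remission-time orderings of Models A, B
and C; LR-test calibration) reproduce directionally.  It does not validate
the models against any real cohort, and the generators deliberately omit
real-data features such as informative visit timing, missing visits,
measurement drift, and covariate feedback.

# Design decisions on genuinely open points

* **Posterior misclassification weights.**  The reported posterior
  $\Pr(S_1 \mid O_2)$ uses length-of-stay proportions of S1 and S2
  renormalized over $\{S_1, S_2\}$ only — the observation $O_2$ already
  excludes S3, so weights over all three states would double-count the
  exclusion.
* **Expanded-model adjacency.**  The raw index-difference rule
  ($|j_r-k_s| = 1$ or $m$) admits wrap-around pairs such as
  $(3,1)\to(1,2)$ at $Y$ boundaries; the implementation uses the lattice
  reading — same $W$ level and $|\Delta j|=1$, or same $Y$ state and
  $|\Delta r|=1$ — which matches the no-simultaneous-moves rule.
* **Damage baselines.**  All four baselines are shared across the 14
  locations; $\lambda_{012}$ and $\lambda_{013}$ are free and
  $\lambda_{024}, \lambda_{034}$ are derived through the symmetry offsets,
  which are time-constant.
* **Model C anchoring.**  Models B and C are two-state alternating panel
  fits of the deterministic recodings; under C the remission state is
  recorded from the first visit of a confirmed run, so the transition is
  automatically interval-censored between the last nonzero-count visit and
  that first zero visit.
* **Non-disease deaths / administrative end** are censoring sets over the
  live states, i.e. treated as independent right censoring.
* **Re-entry after loss to follow-up** is unsupported, and the five-state
  likelihood accepts only the history shapes that scheme can produce.

# Known limitations

Intensities are Markov (no duration dependence) and baselines are limited
to the three families above; emission models beyond the remission
structure are out of scope, as are bootstrap intervals (delta-method
only), continuous fluctuating covariates, and estimation of the
sensitivity parameter $k$, which indexes — rather than resolves — the
unidentifiable dependence between loss to follow-up and the silenced
non-fatal process.
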