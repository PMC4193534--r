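---
title: "Two-stage Bayesian modeling of paired screening tests with unverified double negatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian modeling of paired screening tests with unverified double negatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

## The estimation problem

Population screening programs often apply two cheap, rapid tests
simultaneously to every subject and send anyone positive on either test to
a definitive gold-standard work-up (pancolonoscopy, biopsy, viral culture,
...). Subjects negative on both tests are never verified: working them up
would be costly and, given their low post-test probability of disease,
often unethical. The data such a study yields are a four-cell
cross-classification of the two test results over all `n` subjects
(stage one) and, among the joint positives only, the verified split into
diseased and non-diseased (stage two).

Two features make prevalence and accuracy estimation from these data hard:

* **Partial verification.** The disease status of the double negatives is
  missing by design, so the disease rate in that cell is not identified by
  the likelihood alone.
* **Conditional dependence.** Two tests that share a biological basis (two
  fecal occult blood tests, two antibody assays) tend to err together, both
  within the diseased and within the non-diseased subpopulations. Ignoring
  this dependence biases every estimate.

`dualscreen` estimates the seven base parameters — prevalence $\pi$,
sensitivities $Se_1, Se_2$, specificities $Sp_1, Sp_2$, and the conditional
covariances $covD^+ , covD^-$ between the two test results given disease
and non-disease — from the seven observed counts, resolving the
non-identifiability with probabilistic (prior) constraints rather than by
deterministically simplifying the model.

## The two-stage model

**Stage one.** With test-pattern probabilities built from the covariance
parameterization of two dependent Bernoulli results,

$$Px_{11} = \pi(Se_1 Se_2 + covD^+) + (1-\pi)\{(1-Sp_1)(1-Sp_2) + covD^-\},$$

and analogously for the (+,−), (−,+) and (−,−) patterns (the covariance
enters concordant patterns with a plus sign and discordant ones with a
minus sign), the stage-one counts $(x_{11}, x_{10}, x_{01}, x_{00})$ are
multinomial over all $n$ subjects.

**Stage two.** The joint ("either positive") screen has sensitivity and
specificity

$$Se_{JE} = Se_1 + Se_2 - (Se_1 Se_2 + covD^+), \qquad
  Sp_{JE} = Sp_1 Sp_2 + covD^-,$$

so combining the tests adds sensitivity and sacrifices specificity. With a
perfect gold standard applied to the screen positives, the stage-two counts
$(a_{11}, a_{10}, a_{0.})$ — verified diseased, verified non-diseased,
unverified — are multinomial with cell probabilities
$\pi\,Se_{JE}$, $(1-\pi)(1-Sp_{JE})$ and
$\pi(1-Se_{JE}) + (1-\pi)Sp_{JE}$. The model's observed-data likelihood is
the product of the two multinomial masses; this is the package default
(`factorization = "two-multinomial"`). Because $a_{0.} = x_{00}$ and
$a_{11}+a_{10}$ equals the joint-positive total, the two factors share
margin information; the alternative `factorization = "exact"` replaces the
stage-two multinomial by the binomial split of the verified positives,
which counts each margin exactly once, and is provided for sensitivity
analysis. Multinomial constants are kept in the log-likelihood so that
deviances are comparable across model variants on the same data.

Derived per-draw quantities include the joint PPV
$PPV_{JE} = \pi Se_{JE} / \{\pi Se_{JE} + (1-\pi)(1-Sp_{JE})\}$, the
conditional correlations
$\rho_{D^+} = covD^+/\sqrt{Se_1(1-Se_1)Se_2(1-Se_2)}$ (and its $\rho_{D^-}$
analogue), and the sequential ("joint both") accuracy
$Se_{JB} = Se_{JE}\,Se_{GS}$, $Sp_{JB} = 1-(1-Sp_{JE})(1-Sp_{GS})$. The
gold standard constants default to 1 and are never sampled.

## Priors: the two-step hierarchical uniform

The model has seven free parameters but the known cells carry roughly four
to five degrees of freedom, so informative prior input is unavoidable. The
package follows the principle of placing it where practitioners actually
have it: the **sensitivities**, whose lower bounds can usually be elicited
securely (published evaluations, kit inserts), while a single fixed upper
bound would be a risky guess. The two-step hierarchical uniform prior

$$Se_i \sim U(a_i, b_i), \qquad b_i \sim U(b_{1i}, b_{2i})$$

keeps the secure lower bound and diffuses the upper bound over a
hyperprior. Specificities and prevalence get flat $U(0,1)$ priors — the
simulation study below supports this — and the covariances get
conditionally uniform priors over their feasibility ranges
$0 \le covD^+ \le \min(Se_1,Se_2) - Se_1 Se_2$ (and the $Sp$ analogue),
whose range-dependent normalization is part of the joint density. Beta
priors are deliberately not offered: bounds of a uniform are what
non-statisticians can actually state.

The latent upper bounds are treated as sampled unknowns rather than
marginalized analytically; they appear in the draws as `b_se1`, `b_se2`
but are not headline parameters.

## Posterior computation

`fit_screening()` runs an adaptive Metropolis-within-Gibbs sampler
(implemented in C++) on transformed coordinates:

* log-odds transforms for $\pi$, $Se_i$, $Sp_i$, with uniform/two-step
  support enforced by rejection at the prior, so proposals never hit a
  moving boundary;
* covariances reparameterized as $u = cov/\text{bound} \in (0,1)$. The
  conditionally uniform covariance prior is exactly flat in $u$, which
  removes the changing support from the sampler entirely;
* latent upper bounds mapped to their fixed hyperprior ranges, with the
  constraint $b_i > Se_i$ again enforced by rejection.

Proposal scales adapt toward a 0.44 per-coordinate acceptance rate in
batches of 50 during burn-in only (Robbins–Monro decaying steps), so the
post-burn-in kernel is fixed and the chain's stationary distribution is the
exact posterior. Chains start from independent prior draws — dispersed
starting points by construction — and convergence is monitored by
split-chain potential scale reduction and an initial-positive-sequence
effective sample size; a potential scale reduction above 1.05 on any
headline parameter attaches a warning to the fit rather than failing it.
Defaults are two chains of 105,000 iterations with 5,000 burn-in. The test
suite and the scenario runner use 20,000/2,000, which this sampler mixes
well within for these seven-parameter posteriors; the worked example's full
two-chain run takes seconds.

Seed policy: the configuration seed deterministically derives per-chain
seeds (and, in the scenario runner, per-replicate seeds), so every result
in the package is exactly reproducible from one integer.

## Model checking

No single statistic can validate a partially verified design, so
`evaluate_model()` combines four views:

1. **pD and DIC.** $D(\theta) = -2\log L$; $pD = \bar D - D(\bar\theta)$
   with $\bar\theta$ the posterior mean of the seven base parameters on
   their natural scale; $DIC = \bar D + pD$. A pD near the number of
   effectively identified parameters is healthy; a *negative* pD is a red
   flag for non-identifiability (the plug-in mean falls in a low-density
   fold of a banana-shaped posterior), and the default acceptance band is
   $(0, \text{number of sampled unknowns}]$, configurable because
   "reasonable" is a qualitative judgement.
2. **Local $\chi^2$ posterior-predictive check.** Only the six known cells
   $(x_{11}, x_{10}, x_{01}, x_{00}, a_{11}, a_{10})$ enter the
   discrepancy ($a_{0.}$ duplicates $x_{00}$ and is excluded). For each
   retained draw the observed discrepancy is compared with that of one
   replicated dataset drawn at the same parameters; the reported p-value
   is the fraction of draws where the replicate exceeds the observed.
   Values near 0.5 are ideal; the default acceptance band is
   $[0.05, 0.95]$.
3. **PPV coverage.** The observed PPV $a_{11}/(a_{11}+a_{10})$ is directly
   identified; the 95% credible interval of the model's per-draw
   $PPV_{JE}$ must cover it.
4. **Cell-wise predictive intervals.** Each known cell's observed count
   should fall inside its 95% posterior-predictive interval (default: all
   but at most one cell).

Replicates are generated once per retained draw, by sequential conditional
binomials (vectorized over draws), under a caller-supplied seed. Expected
cells below $10^{-12}$ are skipped with a logged warning rather than
dividing by zero.

## The simulator and the study conditions

`simulate_counts()` draws the latent disease × pattern table from the
eight-cell multinomial implied by the dependence structure and collapses it
exactly as the design observes it, so every count invariant holds by
construction. The scenario presets encode the four canonical study
conditions — prevalence 0.01 with $n = 20000$ or prevalence 0.40 with
$n = 200$, each at high accuracy (0.90/0.95, 0.95/0.90) or low accuracy
(0.60/0.70, 0.70/0.60) — all with conditional correlations
$\rho_{D^+} = 0.5$ and $\rho_{D^-} = 0.4$, values typical of tests sharing
a biological mechanism. Prior modes (`"model"`, `"se"`, `"se2step"`,
`"sp"`) map each canonical true value to its tabulated informative range,
e.g. true $Se = 0.9 \mapsto U(0.85, 0.95)$ or two-step
$U(0.85, U(0.9, 0.99))$.

The dependence-misspecification preset (`"dep"`/`"indep"`) uses moderate
values $\pi = 0.10$, accuracies (0.70, 0.80)/(0.80, 0.70). Its sample size
is not part of the canonical tuples; the package fixes $n = 2000$, a
moderate size between the two canonical designs, chosen once as
representative of a mid-sized screening study.

What the simulator does *not* emulate: covariate-varying accuracy,
imperfect gold standards, verification of a random subset of negatives, or
drift between study stages. Passing recovery tests on these synthetic data
therefore demonstrates correctness of the inferential machinery under the
model's own assumptions, not robustness to real-data violations of them.

## Numerical and design choices

* Cell order is fixed as (11, 10, 01, 00), row-major.
* The covariance feasibility bound is implemented as
  $\min(Se_1,Se_2) - Se_1 Se_2$ (and the $Sp$ analogue); with accuracies
  strictly inside $(0,1)$ the bound is strictly positive, so the $u$
  reparameterization never degenerates.
* Conditional correlations at boundary accuracies (denominator zero) are
  reported as `NaN`, a value rather than an exception.
* A zero-probability cell with a positive count yields a log-likelihood of
  $-\infty$; the sampler treats it as a rejected state.
* `n = 0` data are valid and reproduce the prior — used as a sampler
  self-check in the test suite.
* The identified-limit self-check pins accuracies with width-$10^{-4}$
  uniforms and compares the prevalence posterior against a direct
  quadrature of the likelihood; burn-in is long enough for the proposal
  scales to adapt down to such narrow supports.

## Interval calibration under the two-stage likelihood

Because the two-multinomial formulation counts the shared margins
($a_{0.} = x_{00}$ and the joint-positive total) in both stages, its
posterior is slightly more concentrated than the single-counting exact
factorization. In repeated-sampling checks at the high-prevalence,
small-sample condition ($\pi = 0.4$, $n = 200$) the 95% intervals for
prevalence consequently cover the truth at a rate modestly below nominal
(roughly 80–85% over repeated replicates, versus essentially nominal
coverage under `factorization = "exact"` on the same datasets), while the
accuracy parameters stay at or above nominal coverage. This is a property of the published formulation,
which the package reproduces by default, not of the sampler; users wanting
strictly calibrated intervals for prevalence in small samples can switch
factorizations.

## Known limitations

* Exactly two screening tests; no latent-class extension to three or more.
* The gold standard is assumed perfect for inference; the sequential
  accuracy formulas accept imperfect constants but they are never sampled.
* Informative sensitivity priors are genuinely load-bearing at low
  prevalence: with flat sensitivity priors the sensitivity posteriors span
  most of the unit interval and the prevalence interval inflates by an
  order of magnitude. This is the problem's geometry, not a sampler
  failure, and the prior-sensitivity workflow in the README exists to make
  it visible.
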