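---
title: "Ensemble binding free energies and non-normal assay distributions"
author: "ensembleFE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble binding free energies and non-normal assay distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleFE)
```

# The problem

Binding free energies estimated from molecular dynamics (MD) are chaotic
functionals of the initial conditions: two simulations of the same
ligand--protein system that differ only in their initial velocities drift
apart rapidly, and single-trajectory estimates carry uncontrolled,
unquantified error.  Ensemble protocols address this by running many
replica simulations of the same system and treating the replica as the
statistical unit: the estimate is an ensemble mean, and its uncertainty is
estimated by resampling replicas.

`ensembleFE` implements the analysis half of two such protocols, plus the
statistics needed to compare their output with experiment:

* an **endpoint** (MMPBSA-style) stage that aggregates per-frame energies
  of complex, protein and ligand into an absolute binding free energy;
* an **alchemical** stage that integrates ensemble averages of
  $\partial V/\partial\lambda$ over a fixed $\lambda$ schedule into
  relative binding free energies;
* a **comparison** stage converting assay potencies to free energies and
  quantifying calculation--experiment and platform--platform agreement;
* a **distribution** stage characterizing the decidedly non-normal shape
  of repeatedly measured assay potencies.

Simulation itself (force fields, solvation, the Poisson--Boltzmann solver,
surface-area terms, soft-core potentials) is out of scope: the package
consumes per-frame energy tables and per-window derivative samples, and
ships generators that produce such tables with known ground truth.

# The endpoint estimate

For each frame of each replica, the binding free energy is
$$\Delta G = G_\mathrm{complex} - G_\mathrm{protein} - G_\mathrm{ligand},$$
where each $G$ is the sum of the gas-phase molecular-mechanics energy, the
polar (Poisson--Boltzmann) solvation term and the nonpolar (surface-area)
solvation term; `mmpbsaFrameEnergy()` is that sum and nothing more.  The
configurational-entropy term is deliberately excluded: it rarely improves
affinity rankings, and the class of estimate implemented here omits it (a
hook for a precomputed adaptation term, `includeAdaptation()`, covers the
protein-strain correction instead).

In the one-trajectory mode (the default), protein and ligand energies are
extracted from the complex trajectory, so the three ensembles share
replica ids and frame counts.  `esmacsEstimate()` then averages in a fixed
order: per-frame difference $\to$ per-replica frame mean $\to$ ensemble
mean.  For matched frames this equals the difference of component means,
but it defines the per-replica values that the bootstrap needs.  A
three-trajectory mode averages the three ensembles independently and
combines their standard errors in quadrature.

**Why the bootstrap resamples replicas, not frames.**  Frames within a
replica are autocorrelated (the generator reproduces this with an AR(1)
process), so frame-level resampling understates the error.  Replicas are
launched with independent initial velocities and are the exchangeable unit
of the protocol; `bootstrapSE()` therefore resamples per-replica values
with replacement (default `nBoot = 1000`, seeded; the default is stable to
a few percent on the tested cases).  A documented consequence of the
$1/\sqrt{n}$ behaviour of this error is that 10-replica ensembles carry
standard errors about $\sqrt{25/10} \approx 1.6$ times those of
25-replica ensembles drawn from the same distribution; the acceptance
script measures exactly this ratio.

The **adaptation free energy** (`adaptationFreeEnergy()`) is the
difference between the mean protein free energy in its bound and free
states -- the energetic cost of the conformational strain induced by
binding.  It is computed from two independent ensembles and can be added
to an endpoint estimate, shifting the value by exactly the adaptation term
and combining the errors in quadrature.

# Thermodynamic integration

Alchemical transformations between a pair of compounds are described by a
coupling parameter $\lambda \in [0, 1]$; the free-energy change of a leg
is
$$\Delta G^\mathrm{alch} = \int_0^1
  \left\langle \frac{\partial V(\lambda)}{\partial \lambda}
  \right\rangle_\lambda \, d\lambda,$$
and the relative binding free energy is
$$\Delta\Delta G = \Delta G^\mathrm{alch}_\mathrm{complex}
                 - \Delta G^\mathrm{alch}_\mathrm{aqueous}.$$

The default schedule (`defaultLambdaSchedule()`) has 13 fixed windows,
0.05-spaced near the endpoints and 0.1-spaced in between.  Numerical
choices:

* **Quadrature** is the trapezoidal rule on the schedule nodes.  The
  schedule is fixed by protocol but no quadrature rule comes with it;
  the trapezoid is the standard TI choice, is exact for integrands linear
  in $\lambda$, and on a 13-node schedule its bias for smooth curves is
  well below the statistical error of realistic window sampling.  The
  tests pin the implementation to an independently coded trapezoid oracle
  at $10^{-12}$.
* **Integrate-then-average**: each replica's window means are integrated,
  and the per-replica integrals are averaged and bootstrapped.  Averaging
  first gives the identical point estimate (the quadrature is linear);
  integrating first yields the per-replica distribution the bootstrap
  needs.
* **Leg combination**: the two legs are separate simulations, so
  `tiesEstimate()` sums their variances
  ($se = \sqrt{se_\mathrm{complex}^2 + se_\mathrm{aq}^2}$).
* **Net-charge guard**: pairs whose endpoints differ in net charge are
  refused.  Charge-changing transformations require electrostatic
  finite-size corrections that are not implemented; silently producing an
  uncorrected number would be worse than an error.
* **Missing replicas**: a replica absent from any window is dropped from
  all windows with a warning (or is an error with `strict = TRUE`), so
  every per-replica integral uses the same schedule.

# Comparison with experiment

Assay potencies are converted by
$$\Delta G_\mathrm{exp} = RT \ln \mathrm{IC}_{50}
  = -RT \ln(10)\, \mathrm{pIC}_{50},$$
with $R = 1.9872 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and a default
$T = 300$ K, under the convention that pIC50 is $-\log_{10}$ of the molar
IC50.  One pIC50 unit is then $-1.3727$ kcal/mol at 300 K.  The round trip
pIC50 $\to \Delta G \to$ pIC50 is exact to machine precision.

`comparisonReport()` assembles Pearson and Spearman correlations with 95%
confidence intervals, mean unsigned and signed errors, and an ordinary
least-squares line of calculated on experimental values.  Design choices:

* **CIs by percentile bootstrap** over paired resampling (default
  $10^4$ resamples, seeded).  The data whose comparison this serves are
  demonstrably non-normal, so an interval that assumes normality would be
  self-undermining; a Fisher-z interval is available behind
  `ciMethod = "fisher"` for cross-checking.
* **Censored measurements** ("no activity at the highest tested
  concentration") bound the potency rather than measure it.  They are
  excluded from fitted statistics by default and reported in
  `excludedIds`; `includeCensored = TRUE` retains them.
* **No regression-dilution correction** is applied to the OLS line: the
  correction assumes normally distributed variables, which the
  distribution stage shows is not warranted for this kind of data.

`crossPlatformAgreement()` compares two independent runs of the same
calculations: mean signed/unsigned differences and the fractions of
compounds agreeing within one and two *combined* error bars
($\sqrt{se_A^2 + se_B^2}$ -- each platform contributes its own
uncertainty, so comparing against a single platform's bar would be too
strict).  `outlierOffset()` quantifies a systematic per-compound
discrepancy as the mean of $\Delta\Delta G_\mathrm{calc} -
\Delta\Delta G_\mathrm{exp}$ over the pairs involving the compound, each
pair oriented so the compound is the transformation target; the result is
invariant under reversing any pair.  `stratifyByCharge()` checks the
qualitative electrostatic signal: whether charged compounds are predicted
to bind more favorably than neutral ones.

# Characterizing assay distributions

Repeated measurements of the same compound's pIC50 -- where a compound
has been assayed over a hundred times -- are skewed and heavy-tailed, not
normal.  `summarizeDistribution()` reports:

* **mean** and **SD** (denominator $n - 1$);
* **skewness**: the adjusted Fisher--Pearson standardized third moment
  $G_1 = g_1 \sqrt{n(n-1)}/(n-2)$;
* **excess kurtosis**: the bias-corrected
  $G_2 = \left[(n+1) g_2 + 6\right](n-1)/\left[(n-2)(n-3)\right]$;
* **$\sigma$-bin occupancy**: percentages in the six half-open bins
  $(-\infty, -2\sigma)$, $[-2\sigma, -\sigma)$, $[-\sigma, 0)$,
  $[0, \sigma)$, $[\sigma, 2\sigma)$, $[2\sigma, \infty)$ about the mean,
  where "best-fit normal" means the maximum-likelihood fit, i.e. the
  sample mean and SD;
* the **left $2\sigma$ tail**, compared with the analytic normal value
  2.275%.

The adjusted moment estimators are the common default at
$n \approx 100$--300; the exact estimator convention is isolated in
`sampleSkewness()`/`sampleExcessKurtosis()` so it can be swapped in one
place, and both are pinned to brute-force oracles and to `e1071`'s
type-2 estimators in the tests.  `normalReferenceBins()` provides the
analytic reference row (2.3, 13.6, 34.1, 34.1, 13.6, 2.3 to one decimal).

`kdeHistogram()` summarizes a distribution as a fixed-width histogram
(default bin size 0.05 pIC50 units, edges aligned to multiples of the bin
size) plus a Gaussian KDE.  The bandwidth uses Silverman's rule of thumb:
only the bin size is fixed by convention, and Silverman's rule is the
standard default for unimodal summaries; for strongly skewed samples it
mildly oversmooths the short side, which is acceptable for a descriptive
overlay.

`driftTest()` regresses the measurements on their measurement index and
attaches a two-sided permutation p-value (default $10^4$ seeded shuffles)
rather than the parametric t-test -- assuming normality in the very
analysis that demonstrates non-normality would be circular.  Drift is
modelled as linear in measurement index because nothing firmer than "a
small amount of time dependency" is known about its functional form.

# The synthetic-data generators

Every stage is testable without trajectories because the generators
produce inputs with the statistical structure the analysis assumes, and
record their ground truth in the object metadata (tests never infer truth
from the data):

* `simulateReplicaTraces()` -- replica frame series as stationary AR(1)
  processes (marginal SD `frameSd`, default 2 kcal/mol; lag-1 correlation
  `autocorr`) around replica-level means drawn with spread `replicaSd`
  (default 0.5 kcal/mol) about the role means.  Defaults of 25 replicas
  and 200 frames mirror a 25-replica, 4 ns production ensemble sampled
  every 20 ps.  The AR(1)-plus-offset model is a stand-in for MD noise,
  not a claim about any particular system's error structure: it
  reproduces the two features that matter for the estimator (frame
  autocorrelation and between-replica spread) and none of the systematic
  errors of real force fields.
* `simulateLambdaSamples()` -- window samples around a polynomial
  $\langle \partial V/\partial\lambda\rangle(\lambda)$ whose integral
  over $[0,1]$ is known in closed form.
* `simulateAssayReplicates()` -- draws from a sinh-arcsinh transformed
  location-scale family (see below), plus an optional linear drift.
* `simulateCompoundSet()` -- paired "experimental" and "calculated"
  observations of a known truth, with an optional injected systematic
  outlier offset.

**The sinh-arcsinh family.**  With $Z$ standard normal,
$S = \sinh\left[(\operatorname{asinh} Z + \epsilon)/\delta\right]$ has
polynomial tails in $Z$, so all moments exist for every $\delta > 0$ and
have closed forms in modified Bessel functions
(`sinhArcsinhMoments()`).  The generator solves $(\epsilon, \delta)$
numerically from the requested skewness and excess kurtosis and sets
location and scale analytically, so the *population* first four moments
match the request.  Two numerical points deserve mention:

* No distribution exists with excess kurtosis $\le$ skewness$^2 - 2$;
  such requests fail citing the bound.
* The family's own attainable region is slightly smaller than the
  universal one.  Requests marginally outside it (the package's shape
  tolerance accepts relative errors up to 4% on each coordinate) are
  answered with the nearest attainable shape, which is recorded in the
  returned metadata; requests farther out are errors.  This matters in
  practice: one realistic heavy-tailed target used throughout the tests,
  skewness 2.11 with excess kurtosis 5.30, lies about 1--3% outside the
  region, and the nearest attainable shape (2.05, 5.36) is well within
  the tolerance with which sample moments of $10^5$ draws can be resolved
  anyway.

What the generators do *not* emulate: force-field bias, conformational
trapping, rare-event transitions between binding poses, heteroscedastic
assay noise, batch effects.  Passing recovery tests therefore demonstrates
that the estimators are correct for data satisfying their stated
assumptions -- not that those assumptions hold for any particular
experimental system.

# Problem sizes and tolerances in the test-suite

The test-suite exercises the estimators at sizes where sampling theory
makes the expected accuracy predictable: 20-seed recovery runs for
endpoint ensembles (25 replicas x 200 frames), TI legs (13 windows x 5
replicas x 50--100 samples) and drift detection ($n = 200$); $10^5$-draw
samples for moment recovery (per-seed sample kurtosis of heavy-tailed
distributions still fluctuates by $\pm 0.2$--0.4 at that size, so
recovery is asserted on the 20-seed average); a 200-seed simulation for
the 10-versus-25-replica error-bar ratio; and randomized small instances
for the oracle-equivalence checks at $10^{-9}$ or tighter.  Recovery
within "3 standard errors" allows one excursion per 20 seeds, matching
the nominal coverage of a 3-SE band.

# Limitations

* The endpoint estimate is an approximate endpoint method: no entropy
  term, no explicit water, accuracy limited by the continuum-solvent
  energies it is fed.
* TI here assumes the supplied schedule resolves the integrand; no
  adaptive placement, and no BAR/MBAR-type estimators.
* Charge-changing alchemical pairs are refused rather than corrected.
* The drift diagnostic tests a linear trend only; nonmonotone drifts with
  zero net slope will escape it.
* Descriptive distribution characterization only: the package
  deliberately stops short of a formal normality-test battery, since the
  quantities of interest (moments, bins, tails) are themselves the
  scientific summary.
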