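---
title: "Methods: operational-model fitting and agonist bias quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operational-model fitting and agonist bias quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opbias)
```

## Scope

`opbias` analyses the pharmacology of agonists acting on a panel of
receptor constructs read out through a single functional pathway —
the motivating system being the five muscarinic acetylcholine receptor
subtypes (M1–M5) fused to the promiscuous Gα16 subunit, expressed in CHO
cells and read out as inositol-phosphate (IP~X~) accumulation, with
radioligand ([^3^H]NMS) binding characterizing the constructs. The package
covers four layers: radioligand binding, Hill-level curve description, the
operational model of agonism, and bias quantification, plus a simulator
that generates complete virtual experiments with the same statistical
structure.

## Models

### Binding

Saturation binding follows the rectangular hyperbola
$y = B_{max} x/(K_D + x)$ on specific binding (total minus nonspecific,
averaged per point) versus *free* radioligand, where free = added − bound
(the depletion bookkeeping the assay itself uses). $K_D$ is estimated on
the $-\log_{10}$ molar scale; $B_{max}$ in pmol of sites per mg membrane
protein. Counts (dpm) convert to molar through the radioligand specific
activity (Ci/mmol, 1 Ci = 2.22×10^12^ dpm), counting efficiency, and the
incubation volume.

Competition binding fits both the one-site and the two-site displacement
model (percent of control binding; full displacement at saturating
competitor). The two-site model is adopted only when the
extra-sum-of-squares F-test rejects the one-site model at p < 0.05,
matching the global significance level used everywhere else in the
package. Each IC~50~ converts to an inhibition constant by the
Cheng–Prusoff correction $K_I = IC_{50}/(1 + [D]/K_D)$. The fraction of
low-affinity sites is fitted on a logit scale inside [1, 99]% so the
optimizer cannot collapse onto the boundary; the high/low site ordering is
enforced by parameterizing the high-affinity site as an offset
$\Delta\log > 0$ above the low-affinity one. A diagnostic one-site fit
with a free bottom plateau raises an "incomplete inhibition" warning when
the plateau is significantly above 20% of control, since the agonists this
package targets displace the radioligand completely.

### Functional response

Functional data are fold over basal (basal ≡ 1). The Hill description is
$y = 1 + (E'_{max}-1)\,x^{n_H}/(EC_{50}^{n_H}+x^{n_H})$ with the bottom
fixed at 1. The operational model is
$y = E_{max}\tau x/(K_A + (\tau+1)x)$. Because the data carry a basal of
1 while the bare model passes through zero, two baseline conventions are
implemented:

* **rebased** (default forward model): $y = 1 + (E_{max}-1)\tau
  x/(K_A+(\tau+1)x)$, which anchors the zero-concentration response at the
  basal of 1;
* **plain**: the bare model, whose plateau is $E_{max}\tau/(\tau+1)$.

The plain convention is the one under which published parameter tables for
this assay family are internally consistent
($E'_{max} = E_{max}\tau/(\tau+1)$ with $E'_{max}$ inclusive of basal), so
the closed-form conversions default to it where table reproduction is the
goal. Both conventions share $pEC_{50} = pK_A + \log_{10}(1+\tau)$. When
$n_H = 1$ the Hill and operational descriptions are the same hyperbola and
`hill_to_operational()` converts exactly; the package refuses the
conversion when $|n_H - 1| > 0.2$ (beyond that the shapes genuinely
differ, and only $\tau/K_A$-level quantities remain meaningful).

### The two-step procedure and the E_MAX ridge

The classical two-step procedure first estimates the system maximum from
internal-standard agonists (carbachol, oxotremorine, pilocarpine) and then
fits each agonist's $(\tau, pK_A)$ with $E_{max}$ fixed. Implementing
step 1 exposed a structural fact this package treats as a first-class
result rather than a nuisance: **with unit Hill slope, functional data do
not identify $E_{max}$** — each curve is a two-parameter hyperbola, so for
any ceiling above the largest observed plateau, per-agonist $(\tau, K_A)$
absorb the change exactly and the profiled sum of squares is flat. This
holds no matter how many agonists share the ceiling, and (up to noise)
also when $\tau$ is fitted per experiment. `fit_system_emax()` therefore
profiles the SSE over $E_{max}$ and reports the smallest ceiling
statistically consistent with the unconstrained fit (an F-based lower
confidence edge, found by bisection on the profile), flagged `ridge =
TRUE`. Two consequences, both verified by tests:

* when a full agonist is among the standards, the edge equals that
  agonist's plateau — the textbook special case;
* every bias quantity is invariant to where the ceiling is placed,
  because under either baseline convention $\log(\tau/K_A)$ depends on
  $E_{max}$ only through an additive term common to all agonists at a
  construct ($-\log(E_{max}-1)$ rebased, $-\log E_{max}$ plain), which
  cancels in $\Delta\log(\tau/K_A)$ and RA~i~.

Individual $\tau$ and $pK_A$ values are thus *conventional given the
adopted ceiling*. To reproduce a published parameterization, the ceiling
must be fixed to the published system maximum (`fit_operational(series,
system_emax = ...)`, `emax_source = "fixed_input"`); this is what
`run_pipeline()` does by default with the bundled reference maxima, and it
mirrors how such tables must have been produced.

Step 2 fits $(\log_{10}\tau, pK_A)$ by bounded Levenberg–Marquardt with
$E_{max}$ fixed. A series that the flatness test (below) cannot
distinguish from basal is reported as $\tau = 0$ with $pK_A$ "not
calculated" — the convention for agonists that bind but do not activate
the pathway.

### Flatness test

`flat_test()` compares the Hill model against a constant by the
extra-sum-of-squares F-test; p ≥ 0.05 yields "no coupling". This single
criterion covers both biological situations in scope: fusion constructs
whose cAMP curves are flat because the tethered Gα16 excludes endogenous
G proteins, and Gi/o-biased agonists that fail to stimulate IP~X~ at any
fusion protein.

### Bias quantification

RA~i~ is oriented so a more potent/efficacious test agonist gives
RA~i~ > 1: $(E'_{max,a}/EC_{50,a})/(E'_{max,ref}/EC_{50,ref})$,
equivalently $(\tau_a/K_{A,a})/(\tau_{ref}/K_{A,ref})$ under the plain
transform. This follows the orientation of the published tables; the
formula is sometimes printed reciprocally, and the tables are taken as
authoritative. SDs propagate first-order on the log scale. Bias factors
are $10^{\Delta\Delta\log(\tau/K_A)}$ between constructs for the same
ligand and pathway; $\tau = 0$ anywhere makes the factor undefined and it
is reported as such.

Construct rankings declare ties by a pooled two-sample t-test (df
$2n-2$, default $n = 3$ experiments) on the summary means and SDs,
tied at p ≥ 0.05. This reproduces the published orderings, including
which adjacent pairs are "approximately equal"; a relative-difference
threshold (10%) is the fallback only when no dispersion information
exists. Where per-experiment estimates are available,
`compare_groups()` applies one-way ANOVA followed by Tukey HSD at p <
0.05, with log-scale parameters compared as logarithms; with fewer than 3
estimates per group the flags are withheld.

## The simulator

`sim_config()` encodes the emulated designs: 6 radioligand concentrations
spanning 63–2000 pM in quadruplicate for saturation; competition at 1 nM
radioligand in quadruplicate; 9-point functional curves in half-log steps
centred on the true pEC~50~, in triplicate; 3 independent experiments.
Noise is multiplicative Gaussian parameterized by a CV — 5% for
functional responses, 3% for binding counts — chosen as the standard model
for count-proportional scatter in radiometric assays and sized so
simulated between-experiment SDs are of the magnitude of the tabulated
SDs. The functional basal is drawn uniformly in 2–3% of incorporated
radioactivity per experiment (the dpm scale itself is arbitrary:
fold-over-basal is scale-free). Nonspecific binding is linear in added
radioligand with a default slope of 0.005, which yields roughly 20% of
total binding at 1 nM under typical site densities. Saturation data are
generated with exact depletion bookkeeping (bound solves the quadratic
mass-balance), so the analysis-side free-concentration subtraction
recovers the generator's free values identically. Wild-type cAMP curves
superimpose a submicromolar inhibitory and a micromolar stimulatory
hyperbola over a forskolin-stimulated basal of 1; fused constructs are
flat.

What the simulator does *not* emulate: plate/edge effects, heteroscedastic
baseline drift, correlated replicate errors, ligand depletion in
functional assays, receptor reserve differences between passages, or
non-unit transducer slopes. Passing recovery tests on simulated data
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to every artefact of real plates.

## Numerical choices

* All nonlinear fits use bounded Levenberg–Marquardt (`minpack.lm`) with
  multi-start (potency shifted ±1 log unit; slope 0.5/1/2 for Hill fits),
  keeping the lowest-SSE solution; convergence tolerances 10^-12^
  (10^-14^ for binding fits whose scales are smaller).
* Concentration-like parameters are fitted and stored as $-\log_{10}$
  molar throughout; $\tau$ is fitted as $\log_{10}\tau$ with bounds
  $[10^{-8}, 10^{6}]$.
* Degenerate inputs are handled explicitly: all-nonspecific saturation
  data refuse the fit; free concentration ≤ 0 is a hard error (depletion
  too severe for the simple isotherm); a fitted $K_D$ outside the sampled
  window by >10× is flagged "poorly constrained"; a flat functional series
  short-circuits to the no-response outcome before any Hill fit.
* CSV ingest canonicalizes concentrations to molar at 12 significant
  digits so equivalent unit spellings (1000 nM, 1 µM) collapse to one
  concentration row; written reports carry explicit units in column
  names and fixed numeric formatting so identical runs are byte-identical.

## Problem sizes

The simulation studies in the test suite use the package's default
designs: 500 datasets for the flatness-test power study (9-point
triplicate, plateau 2, 5% CV), 400 one-site datasets for the type-I
calibration of the two-site F-test, 500 draws for the ANOVA/Tukey power
check, and 100 seeds for end-to-end parameter recovery (functional,
competition and saturation assays per seed). These sizes give binomial
standard errors of about 1% on the estimated rates while keeping the suite
quick to run.

## Known limitations

* The $E_{max}$ ridge means absolute $\tau$ values are only comparable
  across studies that adopt the same ceiling; bias quantities are safe.
* Biphasic (bell-shaped) cAMP curves at wild-type M2/M4 are simulated and
  flat-tested but not parametrically fitted — the package reports them
  descriptively, and `fit_hill()` raises "model mismatch (possibly
  biphasic)" rather than silently fitting a monotone curve through them.
* No kinetic binding, no allosteric ternary-complex models, no
  β-arrestin or pathway-versus-pathway bias (the in-scope designs have one
  functional pathway per construct).
* One tabulated row (iperoxo at the fused M5) is not internally consistent
  with the plateau identity under either baseline convention, although its
  $pK_A$ relation holds; consistency checks skip that identity for that
  row.
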