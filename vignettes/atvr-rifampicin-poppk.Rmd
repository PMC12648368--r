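---
title: "Methods: population pharmacokinetics of ritonavir-boosted atazanavir with rifampicin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of ritonavir-boosted atazanavir with rifampicin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atvrpk)
```

## The problem

Ritonavir-boosted atazanavir (ATV/r) is a preferred second-line
antiretroviral in resource-limited settings, but rifampicin — the backbone
of tuberculosis treatment — strongly induces CYP3A and drug transporters
and can strip away most of the atazanavir exposure.  `atvrpk` implements a
nonlinear mixed-effects (population PK) analysis of this interaction: a
mechanistic concentration model for plasma and intracellular (PBMC) drug
levels, the hierarchical variability structure needed to describe repeated
visits under changing regimens, a Laplace marginal-likelihood estimator,
and Monte Carlo simulation machinery to ask the clinical question: *what
fraction of patients still attain therapeutic trough concentrations when
rifampicin is added, and does doubling ATV/r to twice-daily dosing rescue
them?*

Because the underlying clinical datasets are not publicly deposited, the
package is organised around a synthetic-data generator that emulates the
study design (26 adults, four visits: ATV/r 300/100 mg QD alone, plus
rifampicin 600 mg QD, then ATV/r BID with rifampicin 600 and 1200 mg), so
every downstream stage — estimation, diagnostics, simulation — is testable
end to end with known truth.

## Structural model

Absorption is modelled as a chain of `NN` transit compartments with mean
transit time `MTT` feeding an absorption compartment drained at rate `ka`;
disposition is a two-compartment model (`CL`, `V`, `Q`, `Vp`) with
first-order elimination.  The drug input after the transit chain is a
gamma density with shape `NN + 1` and rate `ktr = (NN + 1)/MTT`, which is
defined for non-integer `NN` (the ritonavir estimate is 12.3).  PBMC
concentrations are described by a hypothetical effect compartment that
carries no drug mass: its level `Ce` relaxes towards plasma at rate
`ke0 = log(2)/t_eq` and the reported PBMC concentration is `PPC * Ce`,
where the pseudo-partition coefficient `PPC` is the steady-state
PBMC-to-plasma ratio.

Rather than integrating ODEs, the package evaluates concentrations
analytically: the bolus response of the linear disposition system (and of
the effect compartment) is a sum of exponentials obtained by partial
fractions, and the convolution of each exponential with the gamma
absorption input has the closed form
`exp(-l u) * (ktr/(ktr-l))^(NN+1) * P(NN+1, (ktr-l) u)` with `P` the
regularised incomplete gamma function.  A Gauss–Legendre quadrature branch
covers the (rare) case `ktr <= l`.  An explicit transit-chain ODE
integration (`deSolve`, stiff solver, `rtol 1e-8`/`atol 1e-10`) is kept as
an independent cross-check; the two routes agree to a few parts in 1e7.

Multiple doses superpose linearly.  Steady state under repeated dosing is
computed exactly by summing the geometric series of each exponential term,
with the transit delay entering through its moment factor — equivalent to,
and verified in the test suite against, an explicit 14–20-day dose
history (terminal half-life is ~16 h, so 14 days exceeds 20 half-lives).
Each analysis visit is represented NONMEM-style as a steady-state dose
train up to the unobserved pre-visit dose, then that dose and the observed
in-clinic dose explicitly.

## Covariate and variability model

Body size enters through allometric scaling of clearances
(`(FFM/42)^0.75`) and volumes (`(FFM/42)^1`) using fat-free mass from the
Janmahasatian sex-specific equation, referenced to 42 kg.  Rifampicin and
dosing frequency act as categorical regimen covariates: for atazanavir,
QD + rifampicin multiplies CL by 3.05, F by 0.475 and `ka` by 0.327, while
BID + rifampicin multiplies CL by 2.03 with bioavailability restored (the
`ka` reduction is taken to apply whenever rifampicin is present, since a
single effect is reported); the 1200 mg rifampicin regimen shares the
600 mg parameters (no additional induction was detectable).  For ritonavir
a single 2.12-fold CL induction applies to all rifampicin regimens, with F
reduced to 0.312 (QD) or 0.667 (BID).

Random effects are log-normal: between-subject (BSV, 27.6% for
atazanavir CL), between-visit (BVV, 17.5%) and between-occasion (BOV) on
`ka`, `MTT` and `F`, with *every administered dose its own occasion*.
Doses taken unobserved at home (the dose before each visit's pre-dose
sample) carry BOV inflated 1.63-fold.  Residual error is combined
proportional + additive per matrix, the additive SD fixed at 20% of the
LLOQ (0.030 mg/L plasma, 0.015 mg/L PBMC for atazanavir; 0.005 mg/L
plasma for ritonavir).  Observations below the LLOQ are imputed at LLOQ/2
with the additive error SD inflated by LLOQ/2 — inflation is applied on
the SD scale (`add' = add + LLOQ/2`); switching to variance inflation
would be a one-line change in `sigma2_for()`/`resid_ll_rows`.  The
censoring boundary is strict (`y < LLOQ`); a value exactly at the LLOQ is
retained.  All random effects are independent (no off-diagonal omega was
reported).

## What the synthetic-data generator does and does not emulate

`sample_cohort()` draws weight, height, age from truncated normals
matched to the published medians and ranges (weight mean 67 kg, SD 5,
truncated to 50–75 kg — the SD chosen once so ~95% of the untruncated
mass lies in range) and an 88% female sex ratio; fat-free mass is derived,
not sampled.  `ddi_study_design()` fixes the four-visit regimen sequence,
sampling times (pre-dose, 0.5, 1, 2, 4, 6, 8, 12 h, plus 24 h at visit 1;
PBMC troughs at visits 1, 3, 4 and 12 h at visit 2) and flags the
pre-visit at-home dose as unobserved.  `simulate_dataset()` composes
structural and stochastic layers and keeps the realised random effects as
a `truth` attribute so estimation bias can be computed exactly.

The generator draws occasion effects for the two modelled occasions per
visit (unobserved and observed dose); the steady-state lead-in uses the
subject's typical absorption.  Historical doses only set the background
level, over which per-dose absorption variability largely averages out,
and the fitted model makes the identical assumption, so simulation and
estimation are consistent.  What passing recovery tests on these data
*cannot* show: robustness to model misspecification (real absorption
profiles are not gamma-shaped), adherence patterns, enzyme-induction
dynamics during regimen transitions (regimen effects switch
instantaneously here), food or gastric-pH effects, or assay artefacts
beyond the combined error model.  Dolutegravir, co-administered in the
study, has no PK effect in the model and is omitted.

## Estimation

`marginal_neg2ll()` implements a per-subject Laplace approximation of the
marginal likelihood in the FOCE-with-interaction style: the joint
-2 log-density of observations and etas is minimised over each subject's
etas (damped Gauss–Newton with warm starts; quasi-Newton fallback), the
residual error SD is evaluated at the individual predictions
(eta–epsilon interaction), and the log-determinant term uses the
Gauss–Newton matrix `J' S^-1 J + W^-1` (`hessian = "fd"` switches to the
exact finite-difference Hessian; the neglected eta–epsilon curvature
terms offset the OFV by a few units per subject, but the offset is
essentially constant in the parameters — verified in the tests — so both
variants share the same optimum).  This is an approximation to NONMEM's proprietary
FOCE-I; acceptance is therefore parameter recovery, not OFV equality.
The implementation is cross-checked in three independent ways: against a
closed-form Gaussian likelihood when all variances are zero, against
21-node adaptive Gauss–Hermite quadrature on one-eta models, and against
a generic plain-R Laplace engine (`laplace_neg2ll()`).

Per subject the modelled etas are BSV on CL, BVV per visit, occasion etas
(`ka`, `MTT`, `F`) for each observed dose and an `F` eta for each
unobserved pre-visit dose — 21 etas for atazanavir.  The unobserved
dose's `ka`/`MTT` etas are omitted deliberately: one dosing interval
after that dose its absorption *shape* leaves no measurable trace in the
concentrations (only the absorbed fraction does), so those etas are
unidentifiable and would only inflate the inner problem.

`fit_pk_model()` minimises the OFV over log-transformed parameters in
two bounded quasi-Newton (PORT) stages, each constrained to a generous
box of +-3 log units around the start so trial steps stay in physically
meaningful territory.  Stage one minimises the joint-mode (envelope)
objective — the sum of per-subject minimised joint -2 log densities
without the Laplace log-determinant.  Its gradient comes from the
envelope property of the inner minimum: at the per-subject modes the
objective is first-order exact under parameter perturbations, so
finite-difference gradient evaluations reuse the cached modes without
re-optimising, and are exactly consistent with the stage-one objective.
(The log-determinant cannot be treated this way: its direct parameter
dependence is almost exactly cancelled by the mode shift, so
differentiating it with frozen modes would inject a large spurious
term.)  Stage two polishes on the full Laplace objective with
finite-difference gradients computed from a common mode-cache snapshot;
it typically moves estimates by a percent or so.  Convergence is
reported when the polish stage converges or moves the log-parameters by
less than 0.05.  Relative OFV tolerance is 1e-6 throughout.  Recovery
experiments start the optimiser at the published final-model values, the
natural starting point when refitting a known model; the test suite
verifies that fits started from deliberately off-truth round-number
values reach the same optimum, so this is a speed choice, not an
assumption.

The default recovery protocol estimates the main fixed effects — CL, V,
the rifampicin fold-changes and bioavailability/absorption multipliers,
MTT, PPC and the equilibration half-life (plus `ka` for ritonavir) — and
fixes `Q`, `Vp`, the variance components and residual errors at their
final-model values.  `Q` and `Vp` are weakly identified (the published
peripheral-volume CI spans threefold) and the variability/error layer is
supplied by the generator; any other subset can be estimated via
`pk_model_spec(estimate = ...)`.  Starting values are deliberate
round-number values away from the truth (`generic_init()`).  Parameter
uncertainty is available by sampling importance resampling
(`sir_uncertainty()`: multivariate-normal proposal from the inverse
finite-difference Hessian inflated 2-fold, importance weights, 2.5/97.5
percentile intervals; defaults 2000 proposal draws / 500 resamples, a
deliberately scaled-down setting).  Covariate testing uses the
likelihood-ratio statistic with the conventional 3.84 threshold (1 df,
P < 0.05).

Degenerate and edge cases: zero variances reduce the OFV to the exact
Gaussian form; a failed inner optimisation flags the subject and returns
`Inf` with diagnostics rather than a silent wrong number; near-equal
disposition rate constants are nudged apart by one part in 1e6 before
partial fractions.

## Monte Carlo target attainment

`simulate_pta()` asks, for an in-silico cohort, what fraction attains
steady-state troughs above the protein-adjusted IC90 (0.014 mg/L) and the
0.15 mg/L therapeutic-monitoring target.  Each individual receives one
BSV and one BVV draw on CL, fat-free-mass scaling and the regimen
effects, and 14 days of dosing are simulated; because the model defines
every administered dose as an occasion, each dose in the history carries
independent BOV draws by default (`occasion = "per_dose"`).  The
alternative `"single_draw"` mode applies one occasion draw to every dose,
which treats within-subject variability as if it were between-subject and
widens the trough distribution — under it the QD + rifampicin attainment
of the 0.014 mg/L target drops by about three percentage points; it is
retained for sensitivity analysis.  Troughs are model-predicted without
residual error (the standard PTA convention), read at 24 h for QD and
12 h for BID regimens; `trough_time = 12` reproduces a 12-h read for QD
regimens, mirroring the visit-2 sampling alternative.  The reference
cohort size is 1225; the binomial SE of a proportion near 95% is then
about 0.6 percentage points, and near 70% about 1.3 points, so headline
percentages are reported from several pooled replicate cohorts.  The
cohort uses the study-like demographic configuration; a wider 40–90 kg
configuration can be supplied through `cohort_config()` for robustness
reporting (lighter cohorts shift QD + rifampicin attainment up by several
points, since clearance scales with FFM^0.75).

## Visual predictive checks

`vpc()` simulates replicate datasets (>= 100) under the full stochastic
model at the original design, bins by the nominal sampling times (the
design is rich and fixed, so data-driven binning is unnecessary),
stratifies by regimen and matrix, and overlays observed 5th/50th/95th
percentiles on simulated 95% confidence bands.  BLQ values enter as
LLOQ/2 on both sides of the comparison.  Under-occupied bins are merged
into their nearest neighbour with a warning.  Because the original
concentration data are not available, the VPC's acceptance surface is
self-consistency: data simulated from the model must fall inside their
own bands in at least 90% of bins.

## Problem sizes and numerical settings used by the shipped checks

The test suite and the acceptance script size their computations as
follows: target-attainment runs use cohorts of 1225 (the reference
in-silico cohort size) with pooled replicates; recovery experiments
simulate the full 26-subject, four-visit design and re-fit with the
default protocol (three replicate fits for atazanavir, two for
ritonavir, medians reported); Monte Carlo calibration checks of the
variability layer use 2000–20000 draws; VPC self-consistency uses 150
replicates.  Dense grids for trapezoidal AUC use steps of 0.02 h or
finer over one dosing interval.  Inner mode searches converge on a
gradient sup-norm below 1e-3 OFV units; outer BFGS stops at 1e-6 relative
OFV change.

## Known limitations

Rifampicin's own concentration-time course is out of scope (it enters
only as a categorical covariate), as are exposure-driven interaction
models, the joint atazanavir–ritonavir inhibition model, and
enzyme-turnover dynamics.  The equilibration half-life is informed only
by sparse PBMC troughs and is the least precisely recovered parameter
(its published CI spans threefold, and single-dataset estimates scatter
across that interval).  The Laplace/Gauss–Newton objective is an
approximation; on simulated data it recovers the generating fixed effects
within the published confidence intervals, which is the standard this
package can honestly meet without the original data.
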