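---
title: "Modelling the basal ganglia-thalamocortical inhibition circuit: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the basal ganglia-thalamocortical inhibition circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibcircuit)
```

`inhibcircuit` implements a complete analysis chain for estimating directed
(effective) connectivity in a four-node response-inhibition circuit --
inferior frontal gyrus (IFG), caudate (Cau), globus pallidus (GP), thalamus
(Thal) -- from Go/NoGo fMRI time series: forward simulation of a bilinear
dynamic causal model with a balloon hemodynamic observation model,
single-subject inversion by variational Laplace, and group inference by
parametric empirical Bayes (PEB) with Bayesian model reduction (BMR),
Bayesian model averaging (BMA) and Bayesian contrasts. Because no suitable
public dataset accompanies the problem, the package includes a first-class
synthetic cohort generator whose ground truth mirrors the connectivity
structure the pipeline is designed to detect; every stage is tested against
it.

## The generative model

Neural activity $x \in \mathbb{R}^4$ follows the bilinear form

$$\dot{x} = \Big(A^{*} + \sum_j u_j B_j^{*}\Big)\, x + C u,$$

where $u$ holds the condition inputs (Go and NoGo block boxcars), $A^{*}$
and $B_j^{*}$ denote the effective coupling matrices, and $C$ the driving
inputs. Off-diagonal entries of $A$ and $B_j$ are rates in Hz (the change in
the target region's activity per unit activity of the source region).
Diagonal entries use the standard self-connection convention: they are
unitless log-scaling parameters, and the effective self-connection is
$-0.5\,\mathrm{e}^{a_{ii} + \sum_j u_j b_{j,ii}}$ Hz. This keeps every
self-connection strictly negative for any parameter value; a positive log
parameter means stronger self-inhibition, i.e. reduced sensitivity to the
rest of the network.

Inputs are mean-centered over the session (the default), so $A$ is the mean
effective connectivity across conditions rather than the connectivity in an
implicit baseline condition. One consequence worth knowing: between blocks
the centered inputs are negative constants, so "rest" is itself modelled as
a (small) negative drive.

Each region's BOLD signal arises from the balloon model: vasodilatory
signal $s$, inflow $f$, venous volume $v$ and deoxyhemoglobin content $q$,

$$\dot s = x - \kappa s - \gamma (f - 1), \quad \dot f = s, \quad
\tau \dot v = f - v^{1/\alpha}, \quad
\tau \dot q = f \frac{1 - (1 - E_0)^{1/f}}{E_0} - v^{1/\alpha}\frac{q}{v},$$

observed as percent signal change
$y = 100\,V_0 \big(k_1 (1-q) + k_2 (1 - q/v) + k_3 (1 - v)\big)$ with the
revised coefficients $k_1 = 4.3\,\nu_0 E_0\,\mathrm{TE}$,
$k_2 = \varepsilon r_0 E_0\,\mathrm{TE}$, $k_3 = 1 - \varepsilon$
($\nu_0 = 40.3\,\mathrm{s}^{-1}$, $r_0 = 25\,\mathrm{s}^{-1}$,
$\varepsilon = 1$). Hemodynamic defaults are the canonical published values
($\kappa = 0.64\,\mathrm{s}^{-1}$, $\gamma = 0.32\,\mathrm{s}^{-1}$,
$\tau = 2$ s, $\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$, TE $= 30$ ms);
all are configurable per node, and per-node deviations of $\kappa$ and
$\tau$ are part of the estimable parameter vector.

## Numerical integration

Condition inputs are piecewise constant over microtime bins
(`microtime_dt = TR/16` by default), so the neural substep uses the exact
matrix-exponential propagator of $J(u)$ over one bin; propagators are
cached per distinct input value, which makes repeated simulation cheap
during optimization. The hemodynamic states evolve on time constants of
seconds and are advanced by classical RK4 over two microtime bins, with the
neural drive at the RK4 nodes taken exactly from the microtime grid.
Against a four-fold finer grid this integration scheme agrees to well below
the 1e-4 tolerance the test suite enforces.

The hemodynamic states are integrated as $(s, \log f, \log v, \log q)$.
Positivity of $f$, $v$, $q$ is then structural. This matters because the
balloon model has a genuine domain boundary: sustained neural drive below
$-\gamma$ pushes the inflow fixed point $f^* = 1 + x/\gamma$ negative, where
the equations are meaningless. The integrator detects such excursions
(|log state| > 4) and aborts with an explicit error, exactly as it does
when $|x|$ exceeds its stability bound; silent NaNs never propagate into an
optimization. Gaussian priors do admit unstable draws -- that is a property
of the model class, not a defect -- so the simulation contract is "finite
output or a loud, named failure", and the cohort generator redraws
unstable subjects (up to a bounded retry count).

## Priors and inversion

The estimable vector collects 12 intrinsic couplings, 4 self log-scalings,
32 modulatory entries (Go and NoGo), 8 driving inputs, and 8 hemodynamic
deviations. Default priors are zero-mean Gaussians: variance 1/16 for
couplings, modulations and driving inputs; 1/256 for self log-scalings and
hemodynamic deviations. Observation noise is iid per node with a Gaussian
hyperprior on its log precision, mean 4 and variance 1/2. The mean follows
convention; the variance is deliberately weak because the data are in
percent signal change, where block-design signals of ~1-2% SD put plausible
noise log precisions several nats below 4 -- a tight hyperprior would bias
the noise precision upward and make every posterior overconfident.

`invert_dcm()` maximizes the Laplace free energy $F$ (accuracy minus
complexity) over a Gaussian posterior: Gauss-Newton updates of the
posterior mean with Levenberg damping (damping halves on acceptance,
doubles on rejection), and safeguarded Newton updates of the noise log
precisions. The accepted $F$ trace is non-decreasing by construction, and
the package asserts this on every fit it runs. Convergence is declared
after four consecutive accepted steps improving $F$ by less than 1e-4 nats
(iteration cap 128). Gradients of the forward model are forward finite
differences of the compiled simulator; with propagator caching a full
re-simulation costs about the same as propagating sensitivity equations,
and the single code path is easier to trust. The linear-Gaussian special
case (where Gauss-Newton is exact) is tested against the closed-form
Bayesian regression posterior at 1e-6.

Runs are concatenated with run-wise mean removal of data and prediction
(run-specific baselines) and state resets between runs; no dynamic
carry-over crosses a run boundary. Explained variance is computed on the
run-demeaned data against the posterior-mean prediction, and the
conventional 10% inclusion rule is available as `apply_inclusion_rule()`,
including the behavioral selection-bias check between included and
excluded subjects.

At SNR 1 the single-subject posterior is honest about what the data carry:
driving inputs are well identified, intrinsic couplings reasonably so, and
individual modulatory (B) entries only weakly -- their posterior SDs remain
near the prior SD. Recovery of the circuit should therefore be read at the
cohort level (averaging posterior means over subjects), which is also the
level at which the scientific claims live; the acceptance suite tests
exactly that, plus per-subject sign agreement on the six headline
intrinsic connections.

## The synthetic cohort

`paradigm_spec()` reproduces the mixed block/event Go-NoGo design: two runs
of 12 blocks (6 Go, 6 NoGo, order randomized per run); Go blocks hold 18 Go
trials; NoGo blocks hold 12 Go and 6 NoGo trials (33.3% NoGo within the
block). Trial SOA (2 s), block gap (10 s), lead-in (10 s), tail (16 s) and
TR (2 s) are not published values; they were fixed once as a realistic
event-related regime and are recorded in the spec object.

`default_truth_template()` encodes the qualitative circuit: excitatory
Cau->IFG, Cau->GP, Thal->GP, GP->Thal and a weak Thal->IFG; inhibitory
IFG->Cau and IFG->Thal; self log-scalings negative for IFG/Cau/Thal and
positive for GP; NoGo modulation more inhibitory than Go on IFG->Cau,
IFG->Thal and GP->Cau with negative Cau/Thal self-modulation; NoGo driving
input to all four nodes, Go driving input to IFG only. Magnitudes
(0.1-0.3 Hz) are configuration values chosen once for stability of the
noiseless simulation; they are not published quantities.

`generate_cohort()` adds, per subject: the sex effect (females: -0.1 on the
intrinsic Thal->GP coupling, +0.1 on the NoGo self-modulation of Thal,
i.e. greater thalamic self-inhibition), a performance slope (+0.004 per
percentage point of centered NoGo accuracy on the NoGo modulation of
Thal->IFG), and iid Gaussian deviations (SD 0.05) on all couplings. Noise
is set per node from `SNR = sd(signal)/sd(noise)`, default 1. Behavioral
data are Bernoulli-correct trials at target accuracies (NoGo mean 70.34%,
Go mean 98.47%) with shifted-lognormal reaction times whose mean is about
314 ms. All randomness descends from one master seed through per-subject
substreams, so a cohort is a pure function of its spec.

What the generator deliberately does not emulate: spatially correlated or
temporally autocorrelated noise, scanner drift, motion, emotional-valence
stimulus content, and hemodynamic variability beyond per-node decay and
transit deviations. Passing recovery tests on this cohort therefore show
that the estimator is correct and well calibrated for the generative model
it assumes -- not that real fMRI meets those assumptions.

## Group level: PEB, BMR, BMA, contrasts

`fit_peb()` models selected first-level parameters as
$\theta_i = (x_i^\top \otimes I)\beta + \varepsilon_i$. Each subject's
likelihood contribution is extracted from its (prior, posterior) pair via
the same Gaussian identity that underlies BMR, so nothing is refitted.
Random effects are $\varepsilon_i \sim N(0, e^{-\gamma} V)$ with $V$ set to
1/16 of the first-level prior variances; $\gamma$ carries an $N(0, 1/16)$
hyperprior and is profiled out by maximizing the closed-form second-level
free energy (with a Laplace correction from its numerical curvature). The
$\beta$ prior is zero-mean with the first-level prior variances for every
covariate. Covariates follow the convention: commonalities (constant 1),
sex coded $\pm 0.5$ (female positive), mean-centered NoGo accuracy,
optionally mean-centered age -- so the intercept stays interpretable as the
group mean, and a sex effect reads directly as the female-minus-male
difference. Analyses run separately per parameter block (A, B or C).

`bmr_evidence()` computes the change in log evidence and the implied
posterior under a reduced prior in closed form, with exact handling of
zero-variance (switched-off) parameters via subspace integration; it is
tested to 1e-8 against explicit refits. `greedy_search()` iteratively
prunes group effects: each sweep ranks the still-active effects by the
evidence cost of removing them alone, exhaustively evaluates all on/off
combinations of the eight least-supported ones (256 models), prunes the
effects switched off in the best model, and repeats until the best model
stops improving; the final sweep's family is Bayesian-model-averaged with
softmax weights on free energy. The exploration order (ascending
contribution to $F$) is this package's choice; when fewer than eight
candidates remain in play the family shrinks to $2^k$ and the result is
flagged.

Two framings of evidence coexist deliberately: presence of an effect uses
the model-space posterior probability $P_p$ (summed probability of models
containing it, thresholded at 0.95), while directional condition
comparisons (e.g. NoGo vs Go modulation of one connection) use Gaussian
tail probabilities of a contrast under the BMA. `bayes_factor_null()`
offers the Savage-Dickey density ratio for point-null evidence.

Calibration is tested, not assumed: on cohorts with all group effects set
to zero, covariate effects with $P_p > 0.95$ stay at the nominal ~5% rate,
and recovery/power tests confirm the configured sex, performance and
condition effects are detected with the correct sign. These group-level
studies run on synthetic first-level posteriors
(`simulate_first_level_posteriors()`), which emulate the location and
scale of inversion outputs without their cost or their cross-parameter
correlations -- they test the group machinery in isolation. The full
chain (simulation -> inversion -> group) is exercised by the 20-subject
recovery study.

## First-level GLM and ROI stage

The GLM stage mirrors standard event-related practice: condition boxcars
convolved with a canonical double-gamma HRF at microtime resolution,
sampled at the TR; high-pass filtering by residualization against a
discrete cosine basis (cutoff 128 s, giving `floor(2T/128)+1` columns);
optional confound columns (e.g. six motion parameters) and run intercepts;
OLS with the usual $t = c^\top\hat\beta / \sqrt{\hat\sigma^2 c^\top (X^\top
X)^{-1} c}$. Voxel-level analysis runs on small synthetic 3-D patches, not
whole brains; peak-level family-wise-error correction over a brain volume
is out of scope, and multiplicity on the toy grids is handled by
Bonferroni when needed. ROI definition takes the t-map argmax within
(atlas mask ∩ sphere around the group peak), radius default 2 voxels, with
deterministic lexicographic tie-breaks and a flagged fallback to the group
peak when nothing survives a threshold. Region summaries are first
eigenvariates, sign-aligned with the ROI mean and scaled to its SD --
invariant to voxel ordering. Coordinates are 0-based voxel indices;
millimetre coordinates are metadata only.

## Behavioral statistics

With a two-level within-subject factor, the mixed ANOVA decomposes exactly
into regressions of per-subject difference scores and means on the
centered between-subject terms (sex contrast, age); the inhibition main
effect has df $(1, n-3)$ with sex and age in the model -- at $n = 118$ that
is the printed $(1, 115)$. Partial eta squared uses
$\eta_p^2 = F\,df_1/(F\,df_1 + df_2)$, identical to the sums-of-squares
form. Cohen's d is fixed to the pooled-SD form
$d = (m_1 - m_2)/\sqrt{(s_1^2 + s_2^2)/2}$ with $s = \mathrm{SEM}\sqrt{n}$,
because the printed value is consistent with it at the printed precision;
the formula is documented and the inputs are explicit arguments.

## Problem sizes and runtimes

The test suite runs the full paradigm (2 x 284 volumes, TR 2 s) for the
20-subject recovery study and the acceptance checks, and a scaled-down
4-block variant for unit tests. Single-subject inversion of the full
64-parameter model takes tens of seconds; the whole recovery study
6-15 minutes depending on hardware; group-level calibration and power
studies run on synthetic posteriors in seconds. These sizes were chosen so
the complete suite exercises every stage end to end at realistic
dimensions.

## Known limitations

One-state bilinear deterministic DCM only (no two-state, stochastic,
spectral or nonlinear D-matrix variants); iid observation noise (no AR
modelling); block-level condition inputs for B and C (trial-level events
are used only by the GLM and behavior stages); no spatial preprocessing or
registration; the left-hemisphere control analysis is pure configuration
(the same machinery on a second node set), not a separate implementation.
The inversion's finite-difference gradients assume smoothness of the
forward model in the parameters, which holds everywhere inside the
admissible domain but makes steps near the stability boundary rejection-
prone; the damping loop absorbs this.
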