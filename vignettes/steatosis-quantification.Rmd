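---
title: "Quantifying hepatic steatosis from contrast-enhanced CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic steatosis from contrast-enhanced CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoCT)
```

## The problem

Moderate-to-severe hepatic steatosis (MR-PDFF above 15 percent) can be read
off a non-contrast CT scan: mean liver attenuation below 40 HU is the
accepted imaging reference. Most clinical CT, however, is acquired after
iodinated contrast, which raises liver attenuation by a phase-dependent,
nonlinear amount and invalidates the 40 HU rule. This package implements an
opportunistic-screening workflow for exactly that situation: extract liver
and spleen mean attenuation from labeled volumes or circular ROIs, identify
the contrast phase of a scan from per-slice classifier votes, convert
post-contrast liver attenuation to a non-contrast equivalent, estimate an
MR-PDFF-equivalent fat fraction, and evaluate candidate thresholds with the
standard classification machinery. Everything runs on synthetic phantoms and
simulated cohorts, so the full pipeline is testable without patient data.

## The correction model

For each post-contrast phase $p \in \{\text{arterial}, \text{venous},
\text{delayed}\}$ the non-contrast-equivalent liver attenuation is an
increasing exponential-decay ("saturating exponential") function of the
measured post-contrast value $L'$:

$$L = \alpha_p + \beta_p\,\bigl(1 - e^{-L' \kappa_p}\bigr),$$

with $\beta_p > 0$ and $\kappa_p > 0$, so the curve is strictly increasing
and bounded above by $\alpha_p + \beta_p$. The shipped registry
(`published_models()`) holds the three estimated equations:

| phase    | $\alpha$ (HU) | $\beta$ (HU) | $\kappa$ (HU$^{-1}$) | residual RMSE (HU) |
|----------|---------------|--------------|----------------------|--------------------|
| arterial | −31.478       | 114.8        | 0.022                | 4.7                |
| venous   | −33.488       | 109.094      | 0.015                | 7.4                |
| delayed  | −25.431       | 96.961       | 0.02                 | 4.9                |

The model has an exact algebraic inverse on the open interval
$(\alpha, \alpha + \beta)$,
$L' = -\log\!\bigl(1 - (L - \alpha)/\beta\bigr)/\kappa$, which the simulator
uses to generate post-contrast values from latent non-contrast ones
(`invert_correction()`); `correct_attenuation(invert_correction(x, m), m)`
returns `x` to machine precision across the domain.

Fat fraction is the linear map $FF = -0.58\,L + 38.2$ (percent) applied to
non-contrast or corrected attenuation. The map sends 40 HU to exactly
15 percent, so classifying $FF > 15$ is algebraically the same decision as
classifying $L < 40$; the package keeps both representations and tests their
equivalence. Negative fat fractions (attenuation above roughly 65.9 HU) are
reported with a flag, never clamped: clamping would silently hide implausible
inputs from downstream quality control.

## Fitting the correction equations

`fit_correction()` estimates $(\alpha, \beta, \kappa)$ by unweighted
nonlinear least squares on paired $(L', L)$ observations, minimising the sum
of squared non-contrast residuals. The optimiser is Levenberg–Marquardt with
the analytic Jacobian
$\partial f/\partial\alpha = 1$,
$\partial f/\partial\beta = 1 - e^{-L'\kappa}$,
$\partial f/\partial\kappa = \beta L' e^{-L'\kappa}$,
multiplicative damping, and rejection of steps that leave the admissible
region $\beta > 0$, $\kappa > 0$. Exponential fits of this kind are
sensitive to the rate-constant start, so four deterministic starts are used
($\kappa_0 \in \{0.005, 0.01, 0.02, 0.04\}$, with
$\alpha_0 = \min L - 5$ and $\beta_0 = \mathrm{range}(L) + 10$) and the
lowest-SSE solution wins; this keeps refits reproducible without random
restarts. Convergence is a relative SSE change below $10^{-10}$, capped at
200 iterations per start. Reported RMSE uses divisor $n$, not $n - 3$: the
quantity is used comparatively across cohorts and phases, and the divisor is
documented so the choice cannot silently shift a comparison.

Two independent checks guard the fitter: a brute-force grid search over
$(\alpha, \beta, \kappa)$ boxes (`grid_search_correction()`), which the
fitted optimum must beat or tie on every tested problem, and (in the test
suite only) an off-the-shelf NLS implementation that must agree to $10^{-5}$
on noisy data. Noiseless data regenerate the registry coefficients to
$10^{-6}$.

One identifiability caveat the analysis scripts surface: when the sampled
attenuation range is narrow relative to $1/\kappa$ — as for the venous
curve, whose $\kappa = 0.015$ makes it nearly linear over a screening
cohort's range — the individual coefficients have wide sampling spread even
though the fitted curve and RMSE are tight. Coefficient-recovery statements
in the tests therefore average over replicated simulations (Monte-Carlo
standard errors over 50 seeds) rather than trusting a single refit.

## What the simulators emulate

`simulate_cohort()` draws, per subject, a latent true non-contrast liver
attenuation from a two-component Gaussian mixture: a steatotic component
(default mean 28.8 HU) with weight 0.076 and a non-steatotic component
(default mean 57.9 HU). The component SDs are not separately reported
anywhere we could anchor them, so the package fixes both at 7 HU: the ground
truth label is defined by the 40 HU threshold, and a 7 HU within-component
SD keeps cross-boundary leakage under about 1 percent per component, so
component membership and the threshold label nearly coincide — which is what
the two printed class means describe (they are conditional means of
threshold-defined groups). A larger SD (the printed confidence interval of
the class-mean difference would suggest 9–11 HU pooled, including
between-scanner spread) would decouple component and label and change the
meaning of the configured prevalence.

For each post-contrast phase the simulator inverts the registered correction
model at the latent value to get the post-contrast measurement, and attaches
a paired observed non-contrast value equal to the model forward-evaluation
plus zero-mean Gaussian noise with the phase's residual SD (defaults 4.7,
7.4, 4.9 HU). Noise sits on the non-contrast side because that is the
response variable of the regression the correction equations come from;
refitting the model on simulated pairs is then exactly the estimation
problem the equations solve. One structural consequence is worth stating
plainly: forward-correcting a simulated post-contrast value recovers the
latent attenuation exactly, so corrected-value classification against the
latent truth is near-perfect by construction. End-to-end discrimination
tests on this generator demonstrate that the pipeline composes correctly;
they do not measure the clinical accuracy of the correction, which only
paired patient data can do.

Because the exponential saturates at $\alpha + \beta$, latent values are
restricted to the interval (5 HU, lowest saturation among requested phases
minus 5 HU) by resampling (at most 1000 attempts, then an error). With the
delayed phase included the upper cut sits at 66.5 HU and visibly trims the
upper tail of the non-steatotic component (its realised mean drops by about
1.5 HU); with arterial only, the cut is at 78.3 HU and the effect is
negligible, which is why the mixture-recovery tests use an arterial-only
configuration. Spleen attenuation is drawn independently per phase from
normals whose default means (38.2, 86.0, 99.3, 73.1 HU) follow a worked
single-subject example, with a 6 HU SD chosen as a plausible between-subject
spread; no liver–spleen correlation is modelled, since no such structure was
available to anchor it.

`simulate_phantom()` builds axis-aligned ellipsoidal liver and spleen in an
air background (−1000 HU) with optional voxelwise Gaussian texture and
optional axial cropping that emulates scans whose field of view truncates
the organs. It deliberately does not model anatomy, contrast kinetics,
beam-hardening, or reconstruction-kernel effects: its job is to exercise
masked-mean and ROI extraction, partial-coverage behaviour and the NIfTI
round trip with known ground truth. `simulate_slice_predictions()` likewise
emulates only the statistical shape of a slice-level phase classifier
(per-slice accuracy, confidence distributions), not the classifier itself.

## Attenuation extraction conventions

Volumetric means are plain arithmetic means over all voxels carrying the
organ label; for truncated organs the mean is over the visible labeled
voxels. ROI means pool **all pixels across all ROIs** — a count-weighted
pooled mean, not a mean of per-ROI means — because that is the quantity a
set of manually placed discs measures; pixels covered by overlapping discs
are pooled once per disc (documented so tests can be bit-exact; no guidance
exists on whether or how overlapping manual ROIs were pooled). Discs are 2D
on a single axial slice with pixel-center-in-circle membership, radius
converted from mm via the in-plane spacing. Both extractors are verified
against brute-force voxel/pixel loops on random grids. The liver/spleen
ratio is guarded: a spleen mean within 1 HU of zero is physically
implausible and makes the ratio meaningless, so it is reported as undefined
(the difference is always computed). No HU rescaling happens inside the
extractors; the NIfTI reader is expected to deliver values already in HU.

## Evaluation machinery

Confusion metrics are computed at full precision with undefined (NA) values
for zero denominators, and rounded half-up to one decimal only for
reporting. Thresholds are strict inequalities ("< 40" excludes 40), matching
how clinical thresholds are printed. Threshold sweeps default to 5-HU grids
for attenuation and 5-percent grids for fat fraction, with the
balanced-accuracy optimum and ties broken toward the more specific
threshold. AUROC is the trapezoidal area over all distinct score cutoffs,
which equals the tie-corrected pairwise concordance probability; the test
suite checks this identity to $10^{-12}$ against a brute-force pair loop.
For attenuation-like markers, where low values indicate steatosis, scores
are negated internally so an informative marker always yields AUROC above
0.5. Paired ROC curves are compared with the placement-value (midrank) form
of DeLong's variance estimator; its variance is validated against a
2,000-resample subject bootstrap (within 10 percent) and an independent
implementation. Spearman correlation uses midranks with the
$t$-approximation on $n-2$ degrees of freedom for the p-value. Two-sided
p-values throughout; no multiplicity correction is applied (the evaluation
convention this package mirrors used a 0.01 alpha).

## Pipeline reproducibility

`run_pipeline()` executes the stages (simulate cohort → phantom extraction →
phase vote → correction refit → fat fraction → evaluation) with a single
master seed fanned out as `seed + 100 * stage_index`, so stages are
individually reproducible and never share a stream. Every artifact is CSV
(or JSON for the manifest), and the manifest records the per-stage child
seeds and an md5 checksum per artifact; identical configuration and seed
give byte-identical artifacts. A failing stage aborts the run, names itself,
and leaves a `FAILED` marker beside any partial outputs.

## Problem sizes

The shipped analyses and tests use cohorts of 10,000 subjects for
distribution-level checks, 1,000–2,000 pairs for coefficient-recovery
studies averaged over 50 seeds, 200 phantoms for the ROI-vs-volumetric
correlation study, and 100-instance property sweeps for the oracle
identities. These sizes put Monte-Carlo standard errors comfortably below
the tolerances being asserted while keeping a full run in the order of
seconds to a couple of minutes.

## Limitations

The simulators share the generative assumptions of the correction model
itself; they cannot reveal model misspecification (e.g. scanner- or
kernel-dependent enhancement, heteroskedastic residuals) because none is
injected. Phase identification covers only the voting rule, not the
classifier. The fat-fraction map's validity range is not restricted beyond
flagging: values outside the calibration range of the underlying
CT-to-MR-PDFF relation should be treated as qualitative. Real-cohort
quantities — prevalence under a different case mix, thresholds on other
scanner fleets — are outside what synthetic experiments can establish.
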