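---
title: "A generative model of brain-tissue strain energy functions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generative model of brain-tissue strain energy functions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`elastogen` estimates the elastic parameters of soft tissue from an observed
deformation, by sampling a learned distribution over strain energy density
functions, fitting each sample to a stable constitutive meta-model, simulating
the deformation it implies, and keeping the sample whose simulation best
matches the observation. This vignette documents the model, its assumptions,
the tunable parameters, the numerical choices, and the design decisions that
were genuinely open.

## 1. Constitutive families and stability

Three incompressible hyperelastic families are supported as data sources and
meta-models: neo-Hookean (parameter `mu`, Pa), Mooney–Rivlin (`c1`, `c2`, Pa)
and one-term Ogden (`mu1` in Pa, dimensionless exponent `alpha1`). An
eight-term Ogden evaluator exists only as a "hard" data family; it is never
fitted. MRE and linear-elastic study records are reformulated as neo-Hookean
models through the small-strain identifications `mu = G'` (storage modulus)
and `mu = E / (2(1+nu))`.

Uniaxial curves use the incompressible reduction: axial stretch `l` implies
lateral stretches `l^(-1/2)`, so the triplet is isochoric by construction.

Stability is checked in two layers. Algebraic convexity conditions — `mu > 0`,
`c1 > 0 & c2 >= 0`, `mu1 * alpha1 > 0` — are the conventional sufficient
conditions for these families. On top of that, a numerical Drucker criterion
scans the uniaxial energy on a 201-point grid over `[0.5, 1.5]` (a window
deliberately wider than any fitting window) and requires the energy to be
non-decreasing with distance from the rest configuration on both the
compression and tension sides. `check_stability()` reports violations rather
than raising, because unstable parameter sets are legitimate *inputs* (they
occur in the literature) even though they must never be simulation outputs.

## 2. The synthetic corpus

The real characterisation literature cannot be redistributed, so
`generate_synthetic_corpus()` emulates its statistical shape: 73 models over
12 tasks (MRE / linear / hyperelastic × grey / white / healthy / abnormal),
with per-task counts weighted toward hyperelastic-healthy (18 of 73), the
best-populated corner of the literature. Per-region median shear moduli
default to 1370 Pa (grey, basal ganglia), 990 Pa (white, corpus callosum),
333.28 Pa (healthy) and 2000 Pa (abnormal); individual moduli are drawn
log-normally with `sigma_log = 0.5` (doubled for abnormal tissue, whose
reported properties vary most — the pathologies differ between studies).
Study types observe different strain windows (heterotopic inputs): MRE
`[0.995, 1.005]`, linear `[0.95, 1.05]`, hyperelastic `[0.7, 1.4]`, each
jittered ±20% per model so tasks do not share identical grids. Hyperelastic
studies draw their family as 40% NH / 30% MR / 30% Ogden with
`alpha1 ~ U(-9, -3)`, reflecting the negative Ogden exponents typical of
brain tissue; MR coefficients split the drawn modulus as
`mu = 2(C1 + C2)` and Ogden models as `mu1 = 2 mu / alpha1`, so the
small-strain shear modulus is the quantity the region median controls.

What the generator does *not* emulate: real studies' compression/tension
asymmetry statistics (supported in the data model, off by default),
correlations between region and strain window beyond the study-type defaults,
and the actual per-study parameter values. Tests passing on this corpus show
the pipeline recovers parameters *under the corpus's assumptions*; they do
not certify the literature itself.

## 3. Multi-task GP over log energies

Energy curves are consolidated as `(stretch, ln(Psi + 0.001))` pairs. The
0.001 Pa offset (shared with the meta-model residual) keeps the logarithm
finite at the rest configuration where every energy vanishes. Energies span
orders of magnitude across tasks, which is exactly why regression happens in
log space.

The joint model is an intrinsic coregionalisation model: latent task
functions with covariance `B[t,t'] * k(x, x')`, `B = W W^T + diag(kappa)`
(rank-1 `W`), a Matérn 3/2 kernel `k`, plus per-task Gaussian observation
noise — 2 + 12 + 12 + 12 = 38 free scalars. The Matérn 3/2 choice (once
mean-square differentiable) matches energy curves that bend sharply near
`lambda = 1`. Hyperparameters maximise the log marginal likelihood by
L-BFGS-B on log-transformed parameters (bounds: lengthscale `[1e-4, 10]`,
variances `[1e-8, 1e4]`, `W` in `[-10, 10]`), with seeded random restarts
(default 3) keeping the best optimum; restarts make the best-so-far marginal
likelihood non-decreasing. Cholesky factorisation escalates jitter
`0 -> 1e-10 -> 1e-8 -> 1e-6` (relative to the mean diagonal) before failing.

Two documented choices:

- **Per-task recentring.** Targets are optionally (default on) recentred by
  their task mean before fitting, with the shift undone at prediction. A
  zero-mean prior over raw log energies otherwise forces the kernel variance
  to absorb the large between-task offsets.
- **Training-set thinning.** Each model contributes 100 interpolation points,
  i.e. 7300 training points for the default corpus; a dense Cholesky per
  optimiser step at that size is disproportionate to the smoothness of the
  curves. `fit_gp()` thins evenly to `max_points` (default 600) points. The
  posterior changes negligibly because curves are smooth and massively
  oversampled.

**Envelope sampling.** `sample_offset(gp, task, grid, s)` returns
`exp(mean + s * sd) - 0.001`. The SD is *predictive* (latent posterior
variance plus the task's noise variance): the ±2 SD band then spans the
spread of the literature models feeding the task, which is the uncertainty
the sweep is meant to explore — with the latent SD alone, a well-populated
task would collapse to a sliver around the posterior mean and the sweep
would not bracket plausible tissues. Correlated posterior draws are available
separately (`sample_posterior_draws()`) but the recovery pipeline uses the
deterministic envelope: it is reproducible, and offsets map monotonically to
stiffness, which makes the offset grid an interpretable stiffness sweep.

## 4. Meta-model calibration

Each sampled curve is fitted by up to four meta-models — NH, MR, and one-term
Ogden split at `alpha1 = -5` into a high-exponent and a low-exponent variant —
by bounded Levenberg–Marquardt least squares on residuals
`ln(Psi_model + 0.001) - ln(Psi_sample + 0.001)` with the analytic Jacobian
`(dPsi/dtheta) / (Psi + 0.001)`. Bounds enforce stability: `mu in [1, 1e5]`,
`C1 in [0.5, 5e4]`, `C2 in [0, 5e4]`, Ogden-low `mu1 in [-1e5, -1]` with
`alpha1 in [-30, -5)`. The Ogden-high box `alpha1 in [-5, 30]` contains an
unstable quadrant (`mu1 > 0, alpha1 < 0`), so the fit runs two stable
branches (`mu1 > 0, alpha1 > 0` and `mu1 < 0, -5 <= alpha1 < 0`) and keeps
the cheaper one — returned parameters therefore always satisfy
`mu1 * alpha1 > 0`. Three starts per branch (box midpoint and two log-spaced
interior points) guard against the long narrow cost valleys typical of
hyperelastic calibration. Every fit is re-checked with the Drucker scan on
`[0.5, 1.5]`; family comparison across a corpus uses Kruskal–Wallis with
Bonferroni-corrected pairwise Wilcoxon tests on the fit costs.

## 5. Finite element solver

Deformation is simulated on linear tetrahedra with the compressible
neo-Hookean energy `mu/2 (sum lambda_i^2 - 3) - mu ln J + lambda/2 (ln J)^2`
and a compression-resistance term `k (1-J)^3` active only for `J < 1`
(C2-continuous at `J = 1`, default `k = 10 mu`). Stress is evaluated in the
frame of the rotation-invariant SVD `F = U diag(lambda) V^T`
(`det U = det V = +1`, at most one negative stretch, placed last), which
keeps forces meaningful through element inversion; the first
Piola–Kirchhoff stress is `U diag(dPsi/dlambda) V^T`. Constitutive
evaluation floors stretches at `1e-4` and extrapolates the energy linearly
below the floor, so energy and stress remain consistent for collapsed
elements. Meta-model families enter the same path through their
principal-stretch gradients and Hessians; their volumetric coefficient is
the family's principal stress at the identity (`mu`, `2C1 + 4C2`, `mu1`),
which makes the rest state exactly stress-free, and the Lamé `lambda`
derives from the equivalent small-strain shear modulus
`mu_eff = Psi''_uni(1) / 3` (`mu`, `2(C1+C2)`, `mu1 alpha1 / 2`) at Poisson
ratio 0.49. The near-incompressible 0.49 reflects brain tissue; at
noticeably lower ratios the phantom load regime (Section 7) becomes a
volumetric collapse.

Time integration is implicit backward Euler:
`(M + h D + h^2 K) dv = h (f - R(u) - D v0) - h^2 K v0`, lumped (row-sum)
mass at 1000 kg/m³, Rayleigh damping `D = alpha M + beta K`, Dirichlet rows
and columns projected out (keeping the system symmetric), solved by
Jacobi-preconditioned conjugate gradients. Element tangents are projected to
positive semidefiniteness by eigenvalue clamping at zero (the 3×3 principal
block and the 2×2 twist/flip pairs separately), the standard invertible-FEM
treatment. Internal forces are the exact gradient of the total elastic
energy, and `K` its exact Jacobian away from the clamps — both are verified
against finite differences in the tests.

`simulate_to_equilibrium()` has two modes. `"dynamic"` is plain backward
Euler (the physical transient; total energy decays monotonically under
damping). `"quasistatic"`, the default for equilibrium states, resets the
velocity each step, caps the per-step displacement increment at the
shortest rest edge length (a trust region that keeps intermediate states
physical under crushing loads), and backtracks on the total potential
`E(u) - f^T u`. Both modes converge to the same settled state, and that
state is independent of the step size and damping coefficients (tested); the
quasi-static mode simply reaches it in far fewer steps.

## 6. Phantom and inverse pipeline

The validation phantom is the upper half of an ellipsoid with half-axes
60 × 45 × 40 mm (a brain-scale 120 × 90 × 80 mm solid), meshed by a
structured cube grid with a Kuhn 6-tet split, generated for `x >= 0` and
mirrored so the mesh is exactly symmetric about the mid-sagittal plane. At
the default resolution (16 cells across) it has ~3200 elements. The base
plane is fixed, plus a 2 mm mid-sagittal band of superior nodes as a falx
cerebri proxy; the load set is the superior surface cap (`z` above 55% of
the apex — the cap fraction is exposed since the exact selection in the
source protocol is not). The compression load (default 10 N total) is split
equally over the load nodes, directed inferiorly. Two-tissue phantoms label
a ~10 mm outer shell grey and the core white.

Recovery sweeps the offset grid (±2 SD, step 0.5: 9 candidates per tissue,
81 pairs for two tissues), fits each sample to a neo-Hookean meta-model
(the default; others are available), simulates to equilibrium, and scores by
RMSE over the free surface nodes in mm. One optional refinement pass (on by
default) re-evaluates at half the step around the incumbent best.

Every candidate solve relaxes *from the reference (observed) state* under the
candidate's material, rather than from rest. This is a deliberate protocol
choice with three consequences: all candidates share one deterministic
initial state, so their RMSEs are comparable; the self-recovery candidate
(material equal to the reference's) is an exact fixed point with RMSE zero;
and solves converge in a fraction of the steps of a cold start. Under strong
loads a hyperelastic solid can admit multiple equilibria (post-buckling
branches) — relaxing from the observation selects, for every candidate, the
branch nearest the observation, which is precisely the branch an inverse
problem should score. In the gentle-load regime, where the equilibrium is
unique, the result is identical to a cold start (tested).

## 7. The load regime, and what the tests do and do not show

A genuine limitation deserves plain words. With consistent SI units, a 10 N
compressive load on a brain-sized phantom of a few hundred pascals shear
modulus is a crushing load: the cap pressure (~1.7 kPa) far exceeds the
tissue's shear resistance, the converged equilibrium involves decimetre-scale
displacement, and the inverse problem's RMSE floor is then set by the
candidate grid's stiffness resolution times an enormous sensitivity —
best-sample RMSEs come out in millimetres, not the sub-0.1 mm regime that
motivates the protocol. Conversely, a gentle load (~0.3–0.5 N) on the same
phantom produces millimetre deformations, and there the pipeline resolves a
5% modulus error at ~0.04 mm surface RMSE. The acceptance experiments run
the nominal 10 N protocol regardless and report what they measure; the unit
tests exercise the gentle regime where the inverse problem is
well-conditioned. Users applying the pipeline to their own geometries should
check the ratio of applied pressure to shear modulus before trusting a
recovery.

## 8. Problem sizes and defaults

Defaults were chosen once, as study conditions, and the tests run at them:
73 corpus models; 100 interpolation points per model; GP training thinned to
600 points, 3 restarts; offset grids 9 and 81 with one refinement pass;
phantom resolution 16 (~3200 tets) for acceptance experiments and 8–10 for
unit tests; quasi-static recovery solver with `h = 0.3 s`, CG tolerance
`1e-6` (relative), equilibrium velocity tolerance `1e-5 m/s` (a settled-state
position precision of ~0.003 mm per step, two orders below the RMSE scales
being compared) and a 300-step budget per candidate — candidates that fail
to settle are flagged unconverged and excluded from best-sample selection
(only far-off, very soft candidates ever hit the budget). The full
acceptance pipeline (corpus → GP → two reference states → 9 + 81 solves
with refinement) runs in roughly a quarter hour on one CPU.

## 9. Known limitations

- Clinical-image workflows (registration, segmentation, patient meshing) are
  out of scope; the phantom stands in for a template mesh.
- The corpus is synthetic; conclusions about the real literature require the
  real corpus.
- Linear tetrahedra lock near incompressibility; the compression-resistance
  heuristic mitigates volume loss but does not guarantee preservation.
- The eight-term Ogden family is evaluated, never fitted; none of the
  meta-models can represent it well, which is intentional test data.
- No contact: nothing stops tissue from passing through the base plane under
  extreme loads.
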