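---
title: "Two-stage expansion of a chain released from a spherical cavity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage expansion of a chain released from a spherical cavity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainexpand)
```

## The physical problem

A flexible polymer — think of a single-stranded DNA or RNA genome inside a
ruptured viral capsid — is confined in a spherical cavity at volume fraction
$\phi_0 = N\sigma^3/D^3$ and then suddenly released. `chainexpand` simulates
this release with coarse-grained Langevin dynamics and analyzes the
relaxation with a two-stage kinetic model:

1. **Spherical (first-stage) expansion.** While the chain is still compact
   it swells as a uniform sphere.  Balancing the free-energy release of a
   confined blob liquid against Rouse-type dissipation gives
   $$R(t) = R_0\,(1 + t/\tau_s)^{\alpha},\qquad
     \alpha = \frac{3\nu_b - 1}{6\nu_b + 1},$$
   where $\nu_b$ is the blob scaling exponent ($\nu_b \simeq 1/2$ for a
   melt-like interior, hence $\alpha \simeq 1/8$ as an upper bound and
   $\approx 0.10$ in practice).
2. **Coil (second-stage) expansion.** Once the conformation turns coil-like
   the Flory free energy applies and the kinetic equation integrates to
   $$R(t) = R_F\,\bigl(1 - b_c e^{-t/\tau_c}\bigr)^{\beta},\qquad
     \beta = \tfrac15,\; b_c = 1,$$
   a master curve controlled by the single time $\tau_c$.  The total
   expansion time is defined as $\tau = 3\tau_c$, by which the normalized
   size reaches $(1 - e^{-3})^{1/5} \approx 0.99$.

The second stage dominates: $\tau_s$ is orders of magnitude shorter than
$\tau_c$, so the first-stage variation rides on the principal coil-expansion
curve and joins it on contact — which is exactly how the synthetic-ensemble
generator models the crossover (`max(stage1, stage2)`).

## Model and integrator

The chain is a bead-spring polymer: $N$ beads of diameter $\sigma$ and mass
$m$, purely repulsive WCA excluded volume
($\varepsilon = 1.2\,k_BT$, cutoff $2^{1/6}\sigma$) and stiff harmonic bonds
($b_0 = \sigma$, $k = 6000\,k_BT/\sigma^2$, keeping bond fluctuations under
1% so chain strands cannot cross).  The WCA term acts on every pair, bonded
neighbours included; with this spring constant it merely shifts the
equilibrium bond by about $0.005\,\sigma$.  The thermostat is Langevin with
friction $\eta = 20\,\sqrt{m k_BT}/\sigma$ (an aqueous-like, overdamped
setting) and time step $\Delta t = 0.005\,t_u$, $t_u = \sigma\sqrt{m/k_BT}$.

Integration uses the BAOAB splitting.  At $\eta\Delta t/m = 0.1$ its
free-particle velocity distribution is exact (the O-step is the exact
Ornstein-Uhlenbeck update), and the induced free-particle diffusion constant
deviates from $k_BT/\eta = 0.05\,\sigma^2/t_u$ by less than 0.1%; both
properties are asserted in the test suite.  Pair interactions use a cell
list with edge $\ge 2^{1/6}\sigma$, rebuilt every step and verified
bit-compatibly against a brute-force all-pairs oracle.

The confining wall is purely reflective: a bead whose centre crosses
$D/2 - 0.5\sigma$ (the bead radius is $0.5\sigma$) is mirrored about that
sphere and its radial velocity negated, conserving speed exactly.  The
$-0.5\sigma$ offset follows from assigning the bead a hard radius of
$0.5\sigma$ against the wall; reflection is applied after each position
update rather than by in-step event detection, which is accurate because a
bead travels $\ll \sigma$ per step.  Release simply switches the wall off.

### Preparation of initial states

The cavity-loading process itself (pumping the chain through a pore) is not
simulated: every observable studied here depends only on the equilibrated
confined ensemble.  Confined states are prepared by growing a random walk
inside the cavity with soft self-avoidance, removing residual overlaps with
a short capped-force push-off (cap $10^4\,k_BT/\sigma$, used **only** during
initialization), and equilibrating with the wall on; confined $R_g$ relaxes
on the cavity-diffusion time, far faster than a free coil, and a
stationarity check (no significant linear trend in the last half of the
$R_g^2$ series) guards against under-equilibration.

Free (relaxed-coil) ensembles are a harder sampling problem: the global
conformation of a coil relaxes on the Rouse time
$\sim \eta N^{1+2\nu}$, which is out of reach for plain dynamics at
$N \gtrsim 100$ on a desk budget.  `equilibrium_free_ensemble()` therefore
alternates Metropolis **pivot** moves evaluated on the WCA energy (a pivot
rotation is an isometry of the tail, so only tail-head pair energies enter
the acceptance test) with short Langevin runs that thermalize bonds,
velocities and local structure.  Both kernels preserve the Boltzmann
distribution, and one pivot sweep decorrelates the global shape, so
successive samples are nearly independent equilibrium draws.  The sampler
was validated against long brute-force Langevin equilibration at small $N$
(where the Rouse time is affordable), agreeing on $R_g^2$ and the shape
factors within statistical error.

## Observables

Per snapshot the engine records $R_g^2$ and the gyration tensor
$G_{ab} = \frac1N \sum_i (r_{i,a} - r_{\mathrm{cm},a})
(r_{i,b} - r_{\mathrm{cm},b})$.  Sorted eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ give the asphericity
$$A = \frac{3(\lambda_1^2 + \lambda_2^2 + \lambda_3^2)}
  {2(\lambda_1 + \lambda_2 + \lambda_3)^2} - \frac12 \in [0, 1]$$
and the rescaled prolateness
$P = 27(\lambda_1 - \bar\lambda)(\lambda_2 - \bar\lambda)
(\lambda_3 - \bar\lambda)/(2\lambda_1^3) \in [-1, 1]$, alongside the
conventional $P_c = (\lambda_1-\bar\lambda)(\lambda_2-\bar\lambda)
(\lambda_3-\bar\lambda)/\bar\lambda^3 \in [-0.25, 2]$.  The identity
$\lambda_1 + \lambda_2 + \lambda_3 = R_g^2$ is asserted on every sampled
frame.

Ensemble size is averaged as $R(t) = \langle R_g^2(t)\rangle^{1/2}$ —
mean-then-root, never root-then-mean — with the standard error propagated
from the $R_g^2$ variance.  Shape factors are averaged per snapshot and per
run (computing them from mean eigenvalues instead does not commute with the
nonlinear formulas and gives different numbers; both conventions are
available, and the per-snapshot one is the default).  The expansion
velocity $V_R$ differentiates each replica's $R_g(t)$ with a three-point
formula on a uniform grid *before* ensemble averaging, and $V_R(0) = 0$ is
enforced by the static confined initial condition.  $R_0$ is read off at
$t = 0$; $R_F$ is the mean over the relaxed regime $t/\tau_c > 3$ once
$\tau_c$ is known, or over the trailing 20% of samples (flagged provisional
unless stationary) before a fit — in practice the package measures $R_F$
most cheaply from free-chain equilibrium ensembles, which sample the same
relaxed coil state as a fully expanded release run.

## Fitting machinery

* `diagnostic_F`, `diagnostic_G`, `diagnostic_H` are the exact algebraic
  identities of the two laws: on a perfect stage-2 curve $F \equiv \tau_c$
  and $G \equiv 1/\beta$; on a perfect stage-1 curve $H \equiv \alpha$.
  They are used both as data diagnostics (choosing $\beta = 1/5$ over
  $1/4$ or $1/6$) and as identity tests.
* `fit_stage2` fits $\tau_c$ alone (Levenberg-Marquardt via minpack.lm) on
  the window $t > 0.3\,\hat\tau_c$, iterating until the window is
  self-consistent (relative change $< 0.1\%$).  The window iteration is
  applied here as well as in stage 1 because the stage-2 window also
  depends on its own estimate.
* `fit_stage1` fits $(\tau_s, \alpha)$ on $[0, 10\,\hat\tau_s]$, iterated
  to self-consistency ($< 0.5\%$).  The starting window is seeded from the
  time at which $R/R_0$ first reaches $2^{\alpha_0}$ (with
  $\alpha_0 = 0.1$), i.e. from *below*: starting with a too-large window
  would contaminate the fit with the second-stage regime.  For the
  $\tau_s$-versus-$N$ scaling analysis a two-pass variant is used:
  $\alpha$ and $\tau_s$ are strongly correlated in the free fit, and
  $\alpha$ is expected to be independent of $N$ at fixed $\phi_0$, so the
  per-$N$ $\alpha$ estimates are pooled and $\tau_s$ is refitted with the
  common $\alpha$ (`alpha_fixed`), keeping $\alpha$ noise out of the
  $\tau_s$ ratios that determine the exponent.
* `fit_power_law` is weighted least squares of $\log y$ on $\log x$, with
  1-sigma exponent uncertainties from the linearized covariance.
* `collapse_factor` superposes normalized curves indexed by
  $g = \log_2 N$ after scaling time by $\theta^{g_{\mathrm{ref}} - g}$.
  The objective is the across-curve variance of the interpolated values
  integrated over log scaled time on the common support (the "finest
  neck" criterion); a coarse grid search is refined to a resolution of
  0.01 in the factor.  This objective is the package's own choice of
  collapse criterion; it recovers a constructed factor of $2^{2.36}
  \simeq 5.13$ on synthetic families to within the grid resolution.

## Synthetic ensembles

`synth_ensemble` generates replicas of
$R_g^2(t) = [\max(\mathrm{stage1}, \mathrm{stage2})(t)\cdot\eta(t)]^2$ with
multiplicative log-normal noise (default amplitude 5%, matching the visual
zigzag of single-run curves; optional AR(1) correlation, off by default so
that fitted standard errors remain calibrated).  The noise mean is
corrected so that $E[\eta^2] = 1$, keeping the mean-of-squares estimator
unbiased for the generating curve.  What these fixtures do *not* emulate:
thermal correlations between time points of a real trajectory, the smooth
transient at $t \to 0^+$ (the quasi-equilibrium laws are known not to
describe the first instants), and any $N$- or $\phi_0$-dependence beyond
what the supplied parameters encode.  Passing the recovery tests therefore
validates the estimation machinery, not the molecular model; the
simulation-based acceptance checks do the latter.

## Units

With $\sigma = 3.4\,$Å, $m = 320\,$g/mol and $k_BT = 4.14\times10^{-21}\,$J
(a single-stranded nucleic acid at 300 K), the time unit is
$t_u = \sigma\sqrt{m/k_BT} \approx 3.86\,$ps.  Evaluating the empirical
scaling law $\tau_c \simeq 0.18\,N^{2.36}$ at $N = 1000$ gives
$2.16\times10^6\,t_u \approx 8.35\,\mu$s — a microsecond-order expansion
for a kilobase genome.

## Problem sizes and numerical choices

The reference study runs $N$ up to 512 with 1000 replicas and $10^8$
equilibration steps per condition — cluster-scale work.  The package's own
analyses (tests and `scripts/acceptance.R`) use desk-scale conditions chosen
once and kept fixed:

* free-coil ensembles: $N \in \{32, 64, 128, 256\}$ (plus $N = 512$ for
  the shape factors, matching the chain length at which the reference
  values are defined), 12–24 replicas, hybrid pivot+Langevin sampling
  with 4 burn-in cycles and 12–16 recorded cycles of $4N$ pivot attempts
  plus 2000 dynamics steps each;
* confined ensembles at $\phi_0 = 0.4$: $N \in \{32, 64, 128, 256\}$ plus
  $N = 512$, 10–16 replicas, $0.6$–$1\times10^5$ equilibration steps
  (confined $R_g$ relaxes on the cavity-diffusion time, far faster than a
  free coil);
* first-stage ensembles: $N \in \{32, 64, 128, 256\}$ with 160–240
  release replicas per $N$, harvested as
  16–20 decorrelated snapshots (spaced $2.5\times10^4$ steps) from each of
  10–12 independent equilibration chains, sampled on a dense linear grid
  ($\Delta t_{\mathrm{samp}} \approx \tau_s/25$) because the log grid used
  elsewhere is too sparse for the early-time fit and for three-point
  differentiation;
* second-stage ensembles (test suite): $N \in \{32, 48, 64\}$ with 12–24
  fully independent replicas (the per-replica expansion time depends on
  the initial packed conformation, so equilibration chains are not shared
  here), run lengths of $\sim 2.5\tau_c$, and $R_F$ fixed from large
  free-coil ensembles.  $\hat\tau_c$ responds strongly to $R_F$ errors (a
  1% mis-estimate of $R_F$ moves $\hat\tau_c$ by about 8%), so $R_F$ is
  sampled to $\lesssim 1\%$ standard error.

Degenerate inputs are handled explicitly: eigenvalues are clamped at zero
within $10^{-12}$, diagnostics mask out-of-domain points as `NA` instead of
failing, a curve truncated before its own fit window flags
`converged = FALSE`, and the fixture generator rejects parameter sets whose
two stages are inconsistent at $t = 0$.

## Known limitations

* Small-$N$ scaling windows: exponents fitted over $N \le 256$ carry
  finite-size corrections; the asymptotic second-stage exponent in
  particular is approached from below, so desk-scale estimates of the
  $\tau_c$ exponent sit at the low edge of the reference value.
* The model is athermal and uncharged: no attractive interactions, no
  stiffness, no electrostatics, no hydrodynamic coupling (Rouse dynamics).
* Wall reflection is applied post-step (no in-step event detection).
* Trajectories are reproducible bit-for-bit for a fixed seed and platform,
  but floating-point reductions may differ across compilers.

## A worked example

```{r example, eval = FALSE}
library(chainexpand)
p <- model_params()

snap <- initialize_confined(64, 0.4, p, seed = 1)
eq <- equilibrate(snap, p, cavity_spec(64, 0.4), equil_steps = 6e4,
                  seed = 2)
run <- release_run(eq$snapshot, p, log_times(0.05, 2000), seed = 3)

ens <- run_ensemble(64, 0.4, p, replicas = 24,
                    sample_times = log_times(0.05, 2000), seed = 4)
cur <- ensemble_mean_size(ens)
RF <- estimate_RF(cur)
fit_stage2(cur$t, cur$R, as.numeric(RF))
```
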