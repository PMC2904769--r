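---
title: "How stridegem models the regulation of stride-to-stride variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How stridegem models the regulation of stride-to-stride variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridegem)
```

## The problem

Walking on a motorized treadmill imposes exactly one hard requirement: over
the course of the trial the walker must not reach either end of the belt.
In terms of per-stride quantities — stride time $T_n$ (s), stride length
$L_n$ (m), belt speed $v$ (m/s) — the net displacement in the laboratory
frame after $n$ strides is

$$ d_{net}(n) = \sum_{i \le n} (L_i - v\,T_i), $$

and the requirement is $|d_{net}(n)| \le d_{max}$ for all $n$, with
$d_{max} = 0.864$ m (half the belt length of the treadmill modelled here).
This requirement leaves the walker with a continuum of acceptable strides.
One natural *strategy* for satisfying it is to hold stride speed at the
belt speed on every stride: $L_n / T_n = v$. The set of $(T, L)$ pairs
satisfying this goal exactly is a line — the **goal equivalent manifold
(GEM)** — and any combination of $T$ and $L$ on that line is equally good.
The scientific question the package operationalizes: do walkers regulate
deviations *off* the GEM differently from equally large deviations *along*
it, and what control law reproduces the observed structure?

## GEM decomposition

`fit_gem_frame()` normalizes $T_n$ and $L_n$ to unit variance by dividing
each series by its own SD. This gives both axes a common, dimensionless
dispersion reference ($\sigma = 1$); any common rescaling of both
variables leaves everything that follows unchanged (a property the test
suite asserts). In normalized coordinates the GEM has slope
$\hat m = v\,\sigma_T/\sigma_L$, and the frame's orthonormal basis is

$$ \hat e_T = \frac{(1, \hat m)}{\sqrt{1+\hat m^2}}, \qquad
   \hat e_P = \frac{(-\hat m, 1)}{\sqrt{1+\hat m^2}}. $$

`gem_decompose()` projects each normalized, operating-point-centered
stride onto this basis, producing the goal-equivalent series $\delta_T$
(motion along the GEM; stride speed unchanged) and the goal-relevant
series $\delta_P$ (motion off the GEM; stride speed errors). Because the
transform is a rotation of unit-variance coordinates,
$\mathrm{Var}(\delta_T) + \mathrm{Var}(\delta_P) = 2$ exactly — a useful
internal consistency check.

Two conventions had to be fixed where more than one reasonable choice
exists:

* **Operating point.** Default is the sample mean of the trial; a
  `"projected-to-GEM"` variant ($L^* = vT^*$) is provided. The choice
  shifts $\delta_P$ by an additive constant only, so SDs and DFA exponents
  are identical under both (asserted in the tests).
* **Sign of $\hat e_P$.** Positive $\delta_P$ means the stride was faster
  than the belt. No downstream statistic depends on the sign (SD and DFA
  are sign-invariant); the convention just makes scatter plots readable.

## Detrended fluctuation analysis

Temporal structure is quantified with standard first-order DFA (`dfa()`):
integrate the mean-removed series, split the profile into non-overlapping
boxes of size $n$ taken from the start of the series (the tail remainder
is discarded), remove a least-squares line per box, pool the residual RMS
into $F(n)$, and fit $\alpha$ as the slope of $\log_{10} F$ versus
$\log_{10} n$. Box sizes are ~16 log-spaced integers in $[4, N/4]$: 4 is
the smallest box where a linear fit leaves two residual degrees of
freedom, and $N/4$ guarantees at least four boxes at the largest scale.
The fit uses the full range, unweighted, one point per retained size —
the single-exponent summary used throughout the analysis. Forward-only
boxing was chosen over forward-plus-backward for simplicity; at the
series lengths used here (270–500 strides) the difference is well inside
the stochastic tolerances, and the box-partitioning code isolates the
choice should anyone want to flip it.

Interpretation scale: $\alpha = \tfrac12$ for uncorrelated noise, $>
\tfrac12$ persistence, $< \tfrac12$ anti-persistence, $\approx 1.5$
Brownian motion. Finite series bias the estimator slightly upward
($\approx 0.52$ for iid noise at $N = 500$ with this box range), which is
why calibration statements are made about means over many replicates with
±0.05–0.1 bands rather than about single series.

The independent calibration oracle is `generate_fgn()`: spectral
synthesis of Gaussian noise with power spectrum $f^{-(2H-1)}$, giving
series whose DFA exponent is $H$ by construction ($H > 1$ is generated by
integrating an $H-1$ noise). Spectral synthesis was chosen over
Davies–Harte because ±0.05 accuracy on the mean exponent at $N = 500$ is
all the calibration requires.

## Surrogates

Three surrogate families (`generate_valid_surrogates()`) test
progressively constrained null hypotheses about how strides are chosen:

* **Independent shuffle** — permutes $T$ and $L$ independently: destroys
  temporal order and $T$–$L$ coupling, preserves each marginal
  distribution exactly.
* **Phase-randomized** — randomizes DFT phases of each series separately
  (conjugate symmetry enforced, DC and Nyquist bins untouched): preserves
  each series' full linear autocorrelation while destroying any
  GEM-specific coordination. Simple phase randomization (not
  amplitude-adjusted) is the implemented variant.
* **Paired shuffle** — one permutation applied to both series jointly:
  preserves the $(T, L)$ point cloud, every stride speed, and the
  $\delta_T/\delta_P$ variance ratio exactly, while destroying temporal
  order.

Every surrogate must itself be a physically possible trial: candidates
whose $d_{net}$ would leave the belt, or (phase-randomized only) with
nonpositive $T$ or $L$, are rejected and regenerated, with a per-surrogate
attempt cap (default 1000) and a full rejection report. Twenty surrogates
per trial is the default, and dependent measures are averaged across
them.

## The controller family

Stride-to-stride dynamics are modelled as a discrete map on
$x_n = (T_n, L_n)$:

$$ x_{n+1} = x_n + G\,(I + N)\,u_n + \eta_n, $$

with control input $u_n$, extra plant gains $G = \mathrm{diag}(g_1, g_2)$,
multiplicative (motor-output) noise $N = \mathrm{diag}(\nu_1, \nu_2)$ and
additive (sensory) noise $\eta$; all noise is iid zero-mean Gaussian with
SDs $\sigma_{mult} = (0.017, 0.010)$, $\sigma_{add} = (0.017, 0.010)$.
With no input and no noise, strides repeat — the limit-cycle picture of
steady gait. The controller minimizes the expected single-step cost

$$ C = w_e\,e^2 + w_p\,p^2 + w_{u1} u_1^2 + w_{u2} u_2^2, \qquad
   e = L_{n+1} - v\,T_{n+1}, \quad p = \|x_{n+1} - x^*\|, $$

with weights $w_e = 10$, $w_{u1} = w_{u2} = 10$, and $w_p = 0$ (MIP) or
$2.79$ (POP/OVC); $x^* = (1.105\ \mathrm{s},\ v \cdot 1.105\ \mathrm{m})$,
$v = 1.21$ m/s. The goal error is linear in the state ($e = L - vT$,
proportional to the perpendicular GEM distance), which is what makes the
expected cost exactly quadratic in $u$.

**Formulation choice (genuinely open, decided here).** The minimization
is solved *subject to the equality constraint that the expected goal
error vanish*: $E[e_{n+1}] = 0$ under the controller's internal model of
the plant, which assumes unit gains. The remaining expected cost — the
noise-induced variance terms (the multiplicative noise is
signal-dependent, so $E[C]$ retains curvature in $u$ even on the
constraint), the operating-point pull, and the effort penalties — is then
minimized along the constraint line, giving a closed-form input from a
diagonal 2×2 system plus one Lagrange multiplier
(`optimal_control_input()`). The unconstrained alternative (penalty-only
trade-off of error against effort) was implemented and rejected during
design: at these weights it corrects only ~73% of each perpendicular
deviation, leaving $\alpha(\delta_P) \approx 0.6$ at unit gains and
$\approx 0.53$ at $g = 1.24$ — it cannot produce the anti-persistent
goal-relevant dynamics that the over-correcting variant exists to
produce. Under the constrained form the perpendicular closed-loop pole is
exactly $1 - g$: unit gains give uncorrelated $\delta_P$
($\alpha \approx \tfrac12$), $g > 1$ gives anti-persistence, $g < 1$
persistence — the clean monotone gain dependence that the test suite
asserts over $g \in \{0.8, 1.0, 1.24\}$.

The three presets:

* **MIP** ($w_p = 0$, $G = I$): corrects only goal-relevant error; no
  effort anywhere on the GEM (neutral stability), so $\delta_T$ diffuses
  — $\alpha(\delta_T) \approx 1.5$, $\alpha(\delta_P) \approx 0.5$, and
  the stride cloud is extremely elongated along the GEM.
* **POP** ($w_p = 2.79$): adds a weak pull toward the preferred operating
  point, bounding the tangent drift. The tangent closed-loop pole is
  $1 - w_p/(w_p + w_u) \approx 0.78$, an AR(1) whose DFA exponent at
  $N = 500$ measures just under 1.0 with this package's box range
  (≈0.97–0.99 across seeds) — strongly persistent, but not the pure
  diffusion of MIP. $\alpha(\delta_P)$ stays at ½.
* **OVC** ($g_1 = g_2 = 1.24$): the plant applies 24% more correction
  than the controller planned (the gains model miscalibrated execution,
  not a different plan — the controller still believes $G = I$). Each
  goal-relevant correction overshoots, making $\delta_P$ anti-persistent
  ($\alpha \approx 0.42$) — the signature observed in human treadmill
  walking — while $\delta_T$ remains persistent.

Cost and state are kept in physical units (s, m); the printed weights are
unitful as given. Per-rep RNG streams are derived from `(seed,
rep_index)` so replicates are independent and individually reproducible.
The simulated experiments (`run_model_experiment()`) use 20 replicates of
500 strides; every analyzed replicate must satisfy the belt constraint —
a 500-stride run's $d_{net}$ is a random walk with SD ≈ 0.45 m, so a
belt-violating draw occasionally occurs and is regenerated from the next
derived sub-seed (counted and reported), keeping every analyzed run a
physically completable trial.

## Synthetic data and what passing tests do (and do not) show

`make_humanlike_trial()` produces trials from the OVC preset — the
mechanism in this model family that reproduces the human statistical
signature (persistent $T$ and $L$, anti-persistent $S$, means near
1.105 s / 1.337 m at 1.21 m/s, trial lengths ~213–334 strides with 272 as
the default). Using the model as the generator keeps the repository
self-consistent, but it means end-to-end tests demonstrate that the
pipeline recovers the structure *this controller family produces* — not
that human data contain it. Features of real gait data the generator does
not emulate: measurement noise from marker processing, within-session
drift and fatigue, occasional missteps, inter-subject parameter
variation, and any nonlinear temporal structure beyond the AR-like
dynamics of the stride map. `make_adversarial_trials()` covers the
degenerate branches: zero-variance series (a hard error under SD
normalization rather than a silent fallback to unnormalized units),
too-short series, belt violations, exactly-on-GEM trials (flagged
degenerate for DFA rather than fit to numerical noise), and the
mean-of-speeds vs ratio-of-sums distinction.

## Numerical choices and problem sizes

* Simulated experiments: 20 × 500 strides (a few seconds); DFA
  calibration: 100 replicates of $N = 500$; controller-vs-brute-force
  agreement checked to $10^{-6}$ on 1000 random states per preset against
  a one-dimensional search along the constraint line.
* Degenerate inputs error early with classed conditions
  (`stridegem_degenerate_series`, `stridegem_constant_input`,
  `stridegem_constraint_unsatisfiable`, ...), never silently recover.
* GEM round-trip identity holds to $10^{-10}$; variance partition to
  $10^{-9}$; CSV round-trips exactly (17 significant digits).
* The direction comparison (`direction_anova()`) is a plain two-group
  one-way F test across replicates, $df = (1, 2n-2)$; the original
  analysis's repeated-measures F values had degrees of freedom that a
  2×20 balanced layout does not reproduce, so F statistics here are
  interpreted qualitatively (direction effects are either overwhelming or
  absent) and p-values are reported but never used as acceptance
  surfaces.

## Known limitations

Only the two-dimensional constant-speed GEM is implemented; alternative
goal functions and higher-dimensional manifolds would change `e` and the
frame but not the architecture. DFA is single-exponent (no crossover
segmentation, no multifractal variant). The controller is single-step
with direct state feedback — no observer, no multi-step horizon. The POP
tangent exponent sits just below 1.0 by this package's DFA conventions
and is sensitive to the box-size range and to the exact cost scaling;
treat the tangent exponents of POP/OVC as "strongly persistent" rather
than as a point prediction.
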