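---
title: "Mesoscopic neural-mass models with short-term plasticity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscopic neural-mass models with short-term plasticity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model hierarchy

`mesoreplay` implements one family of models at three levels of
description, all sharing the same physiological parameters.

**Microscopic level.** Each of $N$ linear-nonlinear-Poisson (LNP) neurons
in population $\alpha$ carries the shared input potential $h^\alpha(t)$
(mV) and its own synaptic resource variable $x_j \in [0,1]$
(Tsodyks–Markram depression). In a step $\Delta t$ a neuron spikes with
probability $f(h^\alpha(t^-))\Delta t$ (independent Bernoulli draws); a
spike of neuron $j$ in population $\beta$ makes every potential jump by
$M^{-1} J_{\alpha\beta} U_0 x_j(t^-)/N$ and depletes $x_j$ by
$U_0 x_j(t^-)$; between spikes $h$ and $x_j$ relax with time constants
$\tau$ and $\tau_D$. With facilitation enabled each neuron additionally
carries a utilization variable $u_j$ that jumps by $U(1-u_j)$ per spike
and relaxes to $U_0$ with $\tau_F$, and the released fraction becomes
$u_j x_j$. Neurons within a population share one $h$ exactly (full
connectivity plus identical initial conditions), which is what makes the
population reduction closed.

**Mesoscopic level.** The package's central objects are Langevin equations
for the population means and second moments of the synaptic variables,
driven by two kinds of finite-size noise:

* the *jump-diffusion* model (`simulate_jump_diffusion()`): the population
  activity is Poisson shot noise,
  $A = \Delta n/(N\Delta t),\; \Delta n \sim \mathrm{Pois}(N f(h)\Delta t)$,
  and the across-synapse heterogeneity of the resources enters as Gaussian
  white noise of variance $y f(h)/N$, where $y = Q - x^2$ is the
  population variance of the $x_j$. One stochastic drive realization
  $D = xA + \sqrt{y f(h)/N}\,\xi$ enters the $h$-equation (weighted by
  $M^{-1}J_{\alpha\beta}U_0$) and the own $x$-equation (weighted by
  $-U_0$): the two equations share the same noise, they are not
  independently perturbed.
* the *diffusion* model (`simulate_diffusion()`): for larger $N$ the shot
  noise is itself Gaussian, and the two channels collapse into a single
  white noise with amplitude $\sqrt{Q f(h)/N}$ multiplying $J U_0$ in the
  $h$-equation and $-U_0$ in the $x$-equation (perfectly anticorrelated),
  with the second moment $Q$ integrated as
  $\dot Q = 2(x-Q)/\tau_D - U_0(2-U_0)\,Q f(h)$.
* the *full STP* model (`simulate_full_stp()`): six moments
  $(h, u, x, P, Q, R)$ with two correlated Gaussian channels whose
  correlation is $\rho = (R-ux)/\sqrt{(P-u^2)(Q-x^2)}$, clipped to
  $[-1,1]$. Setting $U = 0$ with $u = U_0$, $P = U_0^2$, $R = U_0 x$
  freezes the utilization moments and recovers the depression-only model
  exactly; the test suite checks this reduction numerically.

The two second-moment bookkeepings ($Q$ versus $y = Q - x^2$) are exact
transforms of each other; the suite integrates both noise-free from
matched initial conditions and verifies $y = Q - x^2$ to the integration
tolerance.

**Macroscopic level.** For $N \to \infty$ all noise amplitudes vanish,
$A = f(h)$, and the skew second-moment equations decouple:
`simulate_macroscopic()` integrates the deterministic two-variable system
per population. Passing `N = Inf` to either stochastic simulator takes the
same limit inside the stochastic kernels; the suite asserts bitwise-level
agreement with the macroscopic integrator.

**Transfer function.** All levels share
$f(h) = r\,a\,\log(1 + e^{(h-h_0)/a})$ (Hz), with threshold-linear limit
$r[h-h_0]_+$ at $a = 0$. It is evaluated piecewise (linear branch plus
`log1p(exp(-z))` correction beyond $z = 30$) so that it neither overflows
nor loses relative accuracy anywhere.

# Units and parameters

Potentials, drives and thresholds are in mV, times in s, rates in Hz.
Coupling constants are specified as the products $J\tau$ (mV), the form in
which they are conventionally tabulated; the effective weight used in the
drift is $J = (J\tau)/\tau$. Under this convention the bistable preset's
high-activity fixed point sits at $h^* = 5.70$ mV with Jacobian
eigenvalues $-1.54 \pm 9.24i$ s$^{-1}$, the anchor the acceptance suite
checks.

`preset_params()` exposes four canonical parameter sets: `"fig2"`
(excitable single population, population spikes), `"fig3"` (bistable
single population, Up–Down switching), `"fig45"` (single-environment ring,
$M = 100$, fluctuation-driven replay at $\mu = -1.4$ mV), and `"fig6"`
(three embedded environments, $M = 300$). The ring presets carry the
deterministic variant's raised drive (`mu_macro`, $-0.9$ and $-0.35$ mV)
used for the fatigue-driven comparison regime.

# Connectivity

`build_single_env_weights()` realizes
$J_{\alpha\beta} = J_1\cos(\theta_\alpha - \theta_\beta) - J_0$ with
place-field angles $\theta_\alpha = 2\pi\alpha/M$: local excitation,
long-range inhibition, a circulant matrix whose Fourier content lives on
modes $0, \pm 1$ only. `build_selectivity()` constructs $K$ embedded maps:
exactly $fM$ populations are selective per environment, and for the
balanced $K = 3$ construction the overlap is symmetric (7 triple-selective
units, 10 per pair, the rest exclusive) so that no environment is
structurally favoured; angles are unique, evenly spaced, and assigned by a
seeded shuffle. The two angles of a pair-selective unit are assigned
independently per environment (global remapping); nothing in the
construction correlates maps. The construction is bit-reproducible from
`(M, K, f, seed)`.

All simulators evaluate the coupling drive through the rank-$2K$-plus-DC
factorization $J = UV^\top - J_0$ in $O(MK)$ per step rather than the
dense $O(M^2)$ product; a dense fallback exists for arbitrary matrices and
the two paths agree to $10^{-12}$ in the tests.

# Numerical scheme and its guard rails

* Forward Euler–Maruyama with $\Delta t = 10^{-4}$ s by default, Itô
  convention: every drift and noise coefficient uses the state at $t^-$.
* Microscopic spike generation is Bernoulli per neuron per step; a step
  with $f(h)\Delta t > 1$ aborts with the step index, $f(h)\Delta t > 0.1$
  is counted and reported as a warning.
* Variance-like quantities ($y$, $Q - x^2$, $P - u^2$) are clamped at 0
  before square roots; $x, u, Q, P$ are clamped to $[0, 1]$; $\rho$ is
  clipped to $[-1, 1]$. Every clamp is counted and returned on the trace
  (`trace$clamp`); under the shipped presets clamping is a rare
  discretization event, and the suite bounds its frequency.
* Default initial conditions: $h$ at the lowest fixed point of the
  macroscopic system under the row-averaged (DC) coupling, $x = 1$,
  $y = 0$ (equivalently $Q = 1$), $u = U_0$, $P = U_0^2$, $R = U_0$; all
  overridable per population.
* Deterministic ring runs add a $10^{-2}$ mV perturbation on spatial
  Fourier mode 1 to the initial potential: the uniform state is an exact
  solution of the noise-free dynamics, so the fatigue-driven
  traveling-wave regime is unreachable without symmetry breaking, while in
  the quiescent regime the perturbation simply decays.
* One R random-number stream drives all channels in a fixed order per step
  (population loop: Poisson count, then Gaussian increments); runs are
  bit-reproducible from `(params, W, T, seed)`. Separate named substreams
  were considered and rejected: base R offers no cheap independent-stream
  API, and reproducibility given the seed — the property the substreams
  would buy — already holds exactly.
* Traces record the activity averaged over the recording stride (default
  1 ms) and sample the remaining state at the stride instants; long ring
  runs can drop the activity matrix (`record = "h"`) since the analysis
  runs on the rate representation (below).

Phase-plane analysis (`find_fixed_points()`) reduces the fixed-point
problem to one scalar equation in $h$ via
$x^*(h) = 1/(1+\tau_D U_0 f(h))$, brackets it on
$[h_0 - 20a - |\mu|,\; h_0 + 5(J\tau)U_0 r + |\mu|]$ with 2000
subintervals, and polishes each root to $10^{-13}$. Stability comes from
the analytic Jacobian (checked against finite differences); manifolds are
traced with an adaptive LSODA integrator from $\pm\varepsilon$ eigenvector
seeds ($\varepsilon = 10^{-6}$), in reversed time for the stable manifold.
The unstable limit cycle bounding the Up state's basin is never computed
explicitly; basin membership is decided by forward integration, which is
robust and sufficient for every statistic the package reports.

# Event statistics: definitions and choices

**Which signal is analysed.** When a trace recorded the potential, every
event statistic runs on the expected rate $f(h^\alpha(t))$
(`replay_summary(on = "auto")`, see `rate_matrix()`); the empirical
spike-count activity remains available (`on = "activity"`). The rate is
the signal the model family's raster displays colour-code, and — being
low-pass filtered by the membrane time constant already — it needs no
arbitrary de-noising kernel: the spike counts at any sub-10-ms resolution
are dominated by Poisson quantization (order one spike per population per
millisecond bin at burst peak).

**Bursts.** Maximal contiguous epochs of the population-averaged signal
above its whole-trace mean, computed after a 5 s burn-in. Epochs separated
by gaps under 10 ms are merged and events under 10 ms discarded
(single-sample threshold chatter); a trace whose total excursion is below
$10^{-3}$ of its mean level counts as constant and yields no events, so a
deterministic run relaxing to a quiescent fixed point reports zero bursts
rather than numerical chatter. For the Up–Down regime a larger merge gap
of 0.3 s is used — about half the period of the damped Up-state focus
oscillation ($\mathrm{Im}\,\lambda/2\pi \approx 1.5$ Hz), whose dips would
otherwise fragment one Up episode into many events.

**Peaks and replay events.** Peaks are local maxima of the event's
population-averaged signal smoothed with a 10 ms moving average, with
minimum topographic prominence 10% of the event's peak height; flat tops
are collapsed to one peak. A burst with more than one peak is a nonlocal
replay event (NLE). The regression of peak count on duration is sensitive
to this choice; the sharp-wave rate during bursts,
$\sum \mathrm{peaks}/\sum \mathrm{duration}$ (`sw_rate`), is robust to it
and is reported alongside.

**Kinematics.** The bump position is the population vector average (PVA),
the argument of $\sum_\alpha A_\alpha e^{i\theta_\alpha}$, computed on the
smoothed activity and sampled once per smoothing window: consecutive
estimates from overlapping windows share their noise, and accumulating arc
length at a finer stride double-counts decoding jitter. Traveled distance
is the total unwrapped arc length, the absolute speed divides it by the
event duration, the signed speed is the net unwrapped displacement per
duration, and forward replay is the anti-clockwise (negative) direction.
Distances exceeding one lap are counted, never clipped.
`decode_trajectory()` implements the complementary step-size analysis:
non-overlapping 50 ms windows (stride = window, matching the discrete
decoded points it emulates), per-window PVA, and a per-event average step
from a straight-line fit to the unwrapped positions.

**Interburst intervals.** Gaps from burst end to next burst start;
cumulants from raw sample moments with no small-sample bias correction,
and from them CV $= \sqrt{\kappa_2}/\kappa_1$, skewness
$\gamma_s = \kappa_3\kappa_2^{-3/2}$, rescaled skewness
$\alpha_s = \gamma_s/(3\,\mathrm{CV})$, kurtosis
$\gamma_e = \kappa_4\kappa_2^{-2}$, rescaled kurtosis
$\alpha_e = \gamma_e/(15\,\mathrm{CV}^2)$ (inverse-Gaussian reference).

**Up–Down segmentation.** The potential histogram (0.1 mV bins, 5-bin
smoothing) is searched for modes on padded log-counts — the Down mode
holds orders of magnitude more mass and may sit at the histogram boundary
— requiring a factor-2 rise over the valley and at least 0.1% of the
samples per mode; the threshold is the inter-mode minimum, and unimodal
histograms are refused (an explicit threshold, e.g. carried over from a
bimodal run at larger $N$, can be supplied instead). Sub-threshold dips
under 0.3 s are absorbed (same focus-oscillation argument as above). The
reported mean covers Up states of at least 1 s. A population spike counts
as followed by an Up state when an Up interval of at least 1 s intersects
the window from burst onset to 200 ms past burst offset.

**Spectra.** `power_spectrum()` is a Welch estimator (Hann taper, 50%
overlap) normalized so the density integrates to the variance. The
Up-state oscillation test restricts the spectrum to Up intervals of at
least 6 s, where the focus rhythm is the dominant peak instead of a
shoulder on the Up–Down switching background.

**Environment sequences.** A burst is attributed to the environment whose
selective populations carry the maximal summed activity during the event
(ties broken to the lowest index and counted); transition matrices are
row-normalized pair counts, and ordered three-distinct-environment
subsequence probabilities divide occurrence counts by (bursts − 2).

# What the generators emulate — and what they do not

The simulators themselves are the package's data generators: the shipped
presets are the study conditions (coupling, drive, $M$, $N$, $dt$ as
tabulated), and the test fixtures (`generate_fixture()`) are analytic
constructions — rectangular pulse trains, a stepping von-Mises-like bump,
i.i.d. environment labels — whose ground truth is known exactly. Passing
tests therefore demonstrate internal consistency of the hierarchy
(micro ↔ meso ↔ macro) and correctness of the statistics on known inputs.
They do not demonstrate biological adequacy: the LNP neuron has no
refractoriness or adaptation, synapses are deterministic
current-based Tsodyks–Markram with full connectivity inside populations,
Dale's law is violated by the Mexican-hat coupling, and the environments
are perfect rings. Conclusions about real hippocampal data require the
caveats of that idealization.

# Problem sizes

The test suite favours short seeded runs whose sampling error is covered
by the stated tolerances: moment oracles use 150–300 s single-population
runs, micro-versus-meso comparisons 400 s, the ring replay reproduction a
single 400 s stretch (~500 bursts), and the Up–Down reproduction 2000 s
per network size. The acceptance script pools four 700 s ring stretches
(~3500 bursts) and one 6000 s Up–Down run (~100 Up episodes), trading a
few minutes of runtime for estimates whose sampling error is small
against the reproduction tolerances. Serial correlations of replay
direction are the one statistic still dominated by sampling noise at
these scales: their true value here is statistically indistinguishable
from zero, and single-run draws scatter by $\pm 1/\sqrt{n_\mathrm{NLE}}$.

# Known limitations

* Forward Euler–Maruyama is first order; halving $dt$ is the only
  convergence control offered. No adaptive stepping.
* The linear filter is the exponential (leaky) kernel only; general
  filters and conductance synapses are out of scope.
* The regression slope of peak count on burst duration depends visibly on
  the peak-counting convention (smoothing width, prominence floor) even
  where every other burst statistic is stable; prefer `sw_rate` when
  comparing across analyses.
* Serialization is delimited text plus YAML metadata; traces are large,
  and long runs should down-sample on write or record only what the
  analysis needs.
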